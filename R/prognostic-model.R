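#' Feature matrix at one axis position
#'
#' Collects, for every animal, the weighted mean and SD of every parameter
#' map at every acquisition day, at one axis position and side. The canonical
#' column layout has 48 predictors: T2 and T2* at D2/D7/D21 (6 parameter-days)
#' plus the nine diffusion scalars at D7/D21 (18 parameter-days), times two
#' statistics, named `<parameter>.<day>.<mean|sd>` in a fixed order that is
#' identical at every position. Animals missing any cell are dropped with a
#' message.
#'
#' @param profiles Profile tibble in the [cohort_profiles()] layout.
#' @param position Axis position (mm); must match the profile grid.
#' @param side `"ipsi"` or `"contra"`.
#' @return Numeric matrix (animals x predictors) with animal ids as row
#'   names; attributes `position`, `side`, `dropped`.
#' @export
assemble_features <- function(profiles, position, side) {
  cols <- feature_columns()
  sub <- profiles[profiles$side == side &
                    abs(profiles$position_mm - position) < 1e-9, ]
  if (!nrow(sub)) stop("no profiles at the requested position/side")
  key <- paste(sub$parameter, sub$day, sep = ".")
  ids <- sort(unique(sub$animal_id))
  X <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, cols))
  for (stat in c("mean", "sd")) {
    v <- if (stat == "mean") sub$wmean else sub$wsd
    cn <- paste(key, stat, sep = ".")
    hit <- cn %in% cols
    X[cbind(match(sub$animal_id[hit], ids), match(cn[hit], cols))] <- v[hit]
  }
  complete <- stats::complete.cases(X)
  dropped <- ids[!complete]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " animal(s) with incomplete features: ",
            paste(dropped, collapse = ", "))
  }
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 3) stop("fewer than 3 animals with complete features")
  structure(X, position = position, side = side, dropped = dropped)
}

#' @rdname assemble_features
#' @export
feature_columns <- function() {
  unlist(lapply(map_parameters(), function(p) {
    unlist(lapply(map_days(p), function(d) paste(p, d, c("mean", "sd"),
                                                 sep = ".")))
  }))
}

#' Inverse-frequency class weights
#'
#' Each observation is weighted proportionally to the inverse frequency of
#' its class, normalized so the weights sum to the number of observations
#' (balanced classes give unit weights).
#'
#' @param labels Binary labels.
#' @return Numeric weight per observation.
#' @export
class_weights <- function(labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  n <- n1 + n0
  ifelse(y == 1, n / (2 * n1), n / (2 * n0))
}

#' Elastic-net logistic regression with nested leave-one-out cross-validation
#'
#' Outer loop: leave-one-out over animals. Within each outer training set the
#' predictors are standardized (mean 0, population SD 1; zero-variance
#' columns are dropped for that fold), observations carry inverse-frequency
#' class weights, and an elastic-net regularization path (mixing
#' `alpha = 0.5`, intercept unpenalized) is fitted with glmnet; the inner
#' cross-validation selects the strength minimizing the binomial deviance
#' (ties broken toward the most regularized model). The held-out animal is
#' scored with that model, and the held-out probabilities are pooled over all
#' outer folds.
#'
#' @param X Numeric matrix (animals x predictors), native units.
#' @param y Binary labels (length `nrow(X)`).
#' @param alpha Elastic-net mixing (0.5 = equal LASSO/ridge weighting).
#' @param inner `"loo"` for leave-one-out inner folds (deterministic), or an
#'   integer k for seeded stratification-free k-fold inner CV.
#' @param nlambda,lambda_min_ratio Regularization grid: `nlambda` values
#'   log-spaced from the smallest strength zeroing all coefficients down by
#'   `lambda_min_ratio`.
#' @param standardize `"fold"` (per outer training set; default) or
#'   `"global"` (once on the full data; exposed for leakage comparisons).
#' @param seed Seed for the inner fold assignment when `inner` is a count;
#'   LOO itself is deterministic.
#' @return A `model_result`: `prob` (pooled out-of-fold probability per
#'   animal), `y`, `auc` (pooled), `lambda` (selected strength per fold),
#'   `coefs` (folds x predictors, standardized scale), `alpha`.
#' @export
nested_loocv_elastic_net <- function(X, y, alpha = 0.5, inner = "loo",
                                     nlambda = 100, lambda_min_ratio = 1e-4,
                                     standardize = c("fold", "global"),
                                     thresh = 1e-7, seed = NULL) {
  standardize <- match.arg(standardize)
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (n < 6) stop("need at least 6 animals for nested LOOCV")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 animals per class")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  p <- ncol(X)
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(p))
  if (standardize == "global") {
    mu_g <- colMeans(X)
    sd_g <- sqrt(colMeans(sweep(X, 2, mu_g)^2))
  }
  prob <- numeric(n)
  lam <- numeric(n)
  coefs <- matrix(0, n, p, dimnames = list(NULL, cn))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (standardize == "fold") {
      mu <- colMeans(Xtr)
      sdv <- sqrt(colMeans(sweep(Xtr, 2, mu)^2))
    } else {
      mu <- mu_g; sdv <- sd_g
    }
    keep <- sdv > 0
    w <- class_weights(ytr)
    if (!any(keep)) {
      # no informative predictor: weighted training prevalence
      prob[i] <- sum(w * ytr) / sum(w)
      lam[i] <- NA_real_
      next
    }
    Z <- sweep(sweep(Xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], `/`)
    zi <- (X[i, keep] - mu[keep]) / sdv[keep]
    m <- nrow(Z)
    foldid <- if (identical(inner, "loo")) seq_len(m) else {
      k <- as.integer(inner)
      sample(rep_len(seq_len(k), m))
    }
    fit_full <- tryCatch(
      suppressWarnings(glmnet::glmnet(Z, ytr, family = "binomial", alpha = alpha,
                     weights = w, nlambda = nlambda,
                     lambda.min.ratio = lambda_min_ratio,
                     standardize = FALSE, thresh = thresh)),
      error = function(e) NULL)
    if (is.null(fit_full) || length(fit_full$lambda) == 0) {
      prob[i] <- sum(w * ytr) / sum(w)
      lam[i] <- NA_real_
      next
    }
    lam_seq <- fit_full$lambda
    # inner CV: refit on each inner-training set over the shared lambda
    # path and accumulate the class-weighted binomial deviance of the
    # held-in-fold predictions
    dev <- rep(0, length(lam_seq))
    dev_n <- rep(0, length(lam_seq))
    for (f in sort(unique(foldid))) {
      intr <- foldid != f
      if (length(unique(ytr[intr])) < 2) next  # single-class inner fold
      fit_f <- tryCatch(
        suppressWarnings(glmnet::glmnet(Z[intr, , drop = FALSE], ytr[intr],
                                        family = "binomial", alpha = alpha,
                                        weights = w[intr], lambda = lam_seq,
                                        standardize = FALSE,
                                        thresh = thresh)),
        error = function(e) NULL)
      if (is.null(fit_f)) next
      eta <- sweep(Z[!intr, , drop = FALSE] %*% fit_f$beta, 2, fit_f$a0, `+`)
      pf <- 1 / (1 + exp(-as.matrix(eta)))
      pf <- pmin(pmax(pf, 1e-12), 1 - 1e-12)
      yv <- ytr[!intr]; wv <- w[!intr]
      dcontr <- -2 * colSums(wv * (yv * log(pf) + (1 - yv) * log(1 - pf)))
      nl <- ncol(pf)
      dev[seq_len(nl)] <- dev[seq_len(nl)] + dcontr
      dev_n[seq_len(nl)] <- dev_n[seq_len(nl)] + sum(wv)
    }
    if (all(dev_n == 0)) {
      prob[i] <- sum(w * ytr) / sum(w)
      lam[i] <- NA_real_
      next
    }
    cvm <- ifelse(dev_n > 0, dev / dev_n, Inf)
    # most-regularized strength among the inner-deviance minimizers
    sel <- min(which(cvm <= min(cvm) + 1e-12))
    lam[i] <- lam_seq[sel]
    cf <- as.numeric(fit_full$beta[, sel])
    prob[i] <- 1 / (1 + exp(-(fit_full$a0[sel] + sum(zi * cf))))
    coefs[i, keep] <- cf
  }
  structure(list(prob = stats::setNames(prob, rownames(X)), y = y,
                 auc = empirical_auc(prob, y), lambda = lam, coefs = coefs,
                 alpha = alpha, position = attr(X, "position"),
                 side = attr(X, "side")),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("model_result: n = %d, pooled LOOCV AUC = %.3f\n",
              length(x$prob), x$auc))
  invisible(x)
}

#' Pooled AUC with a BCa bootstrap confidence interval
#'
#' Resamples animals (their label and pooled out-of-fold probability) with
#' class stratification and forms the bias-corrected and accelerated
#' interval.
#'
#' @param result A `model_result`.
#' @param n_boot Bootstrap resamples (default 10,000).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List with `auc`, `lower`, `upper`, `method`, `flagged`.
#' @export
model_auc_with_ci <- function(result, n_boot = 10000, level = 0.95,
                              seed = NULL) {
  stopifnot(inherits(result, "model_result"))
  ci <- bootstrap_auc_ci(result$prob, result$y, n_boot = n_boot,
                         level = level, seed = seed)
  list(auc = ci$auc, lower = ci$lower, upper = ci$upper,
       method = ci$method, flagged = ci$flagged)
}

#' Fold-averaged coefficient importance
#'
#' Averages the standardized coefficients over the outer cross-validation
#' folds and ranks predictors by largest absolute averaged coefficient. For a
#' list of results (e.g. a position sweep) a predictor qualifies by its best
#' position.
#'
#' @param result A `model_result` or a list of them.
#' @param k Number of top predictors to select.
#' @return Tibble: predictor, position, avg_coef, abs_coef, rank. Attribute
#'   `all_zero` is `TRUE` when every averaged coefficient is zero (fully
#'   regularized models), in which case the tibble is empty.
#' @export
coefficient_importance <- function(result, k = 5) {
  results <- if (inherits(result, "model_result")) list(result) else result
  stopifnot(length(results) > 0)
  per_pos <- lapply(results, function(r) {
    tibble::tibble(predictor = colnames(r$coefs),
                   position = if (is.null(r$position)) NA_real_ else r$position,
                   avg_coef = colMeans(r$coefs))
  })
  tab <- dplyr::bind_rows(per_pos)
  tab$abs_coef <- abs(tab$avg_coef)
  best <- dplyr::slice_max(dplyr::group_by(tab, .data$predictor),
                           .data$abs_coef, n = 1, with_ties = FALSE)
  best <- dplyr::arrange(dplyr::ungroup(best), dplyr::desc(.data$abs_coef))
  nonzero <- best[best$abs_coef > 0, ]
  out <- utils::head(nonzero, k)
  out$rank <- seq_len(nrow(out))
  attr(out, "all_zero") <- nrow(nonzero) == 0
  out
}

#' Prognostic model on hippocampal volumes
#'
#' The same nested-LOOCV elastic-net machinery applied to the six volume
#' predictors (2 sides x 3 days).
#'
#' @param volumes Numeric matrix (animals x 6) or the tidy tibble from
#'   [cohort_volumes()] (animal_id, side, day, volume_mm3).
#' @param labels Binary labels per animal (or a label tibble plus
#'   `contrast`).
#' @param contrast When `labels` is a label tibble: which contrast to model.
#' @param ... Passed to [nested_loocv_elastic_net()].
#' @return A `model_result`.
#' @export
volume_model <- function(volumes, labels, contrast = NULL, ...) {
  if (is.data.frame(volumes)) {
    wide <- tidyr::pivot_wider(volumes,
                               id_cols = "animal_id",
                               names_from = c("side", "day"),
                               values_from = "volume_mm3",
                               names_sep = ".")
    ids <- wide$animal_id
    volumes <- as.matrix(wide[, -1])
    rownames(volumes) <- ids
  }
  if (anyNA(volumes)) stop("volume table is incomplete")
  if (is.data.frame(labels)) {
    stopifnot(!is.null(contrast))
    gr <- contrast_groups(labels, contrast)
    keep <- rownames(volumes) %in% c(gr$a, gr$b)
    volumes <- volumes[keep, , drop = FALSE]
    y <- rownames(volumes) %in% gr$b
  } else {
    y <- labels
  }
  nested_loocv_elastic_net(volumes, y, ...)
}

#' Model sweep along the septotemporal axis
#'
#' Fits one nested-LOOCV elastic-net model per (side, position), pools the
#' out-of-fold probabilities, and computes the BCa bootstrap CI of each
#' pooled AUC. A position is flagged as discriminative when the lower CI
#' bound exceeds 0.5.
#'
#' @param profiles Profile tibble.
#' @param labels Label tibble.
#' @param contrast `"sham_tbi"`, `"tbi_epilepsy"` or `"ci"`.
#' @param positions Axis positions (mm) to model.
#' @param sides Sides to sweep.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Master seed; each (side, position) gets a derived seed.
#' @param ... Passed to [nested_loocv_elastic_net()].
#' @return List with `results` (named list of `model_result`) and `summary`
#'   (tibble: side, position_mm, n, auc, auc_lo, auc_hi, flagged).
#' @export
position_sweep <- function(profiles, labels, contrast, positions,
                           sides = c("ipsi", "contra"), n_boot = 10000,
                           seed = 1, ...) {
  gr <- contrast_groups(labels, contrast)
  results <- list()
  rows <- list()
  ctr <- 0L
  for (side in sides) {
    for (pos in positions) {
      ctr <- ctr + 1L
      X <- assemble_features(profiles, pos, side)
      keep <- rownames(X) %in% c(gr$a, gr$b)
      X <- X[keep, , drop = FALSE]
      y <- rownames(X) %in% gr$b
      fit <- nested_loocv_elastic_net(X, y, seed = seed + ctr, ...)
      fit$position <- pos; fit$side <- side; fit$contrast <- contrast
      ci <- model_auc_with_ci(fit, n_boot = n_boot, seed = seed + 10000L + ctr)
      key <- sprintf("%s_%s", side, format(pos))
      results[[key]] <- fit
      rows[[key]] <- tibble::tibble(side = side, position_mm = pos,
                                    n = nrow(X), auc = ci$auc,
                                    auc_lo = ci$lower, auc_hi = ci$upper,
                                    flagged = ci$lower > 0.5)
    }
  }
  list(results = results, summary = dplyr::bind_rows(rows))
}
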