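#' Mann-Whitney U test for two samples
#'
#' Thin, contract-checked wrapper around [stats::wilcox.test()]: exact
#' two-sided p-values for small untied samples, normal approximation with tie
#' and continuity correction otherwise. The returned `U` counts pairs in
#' which an `a` observation exceeds a `b` observation (ties count 1/2), so
#' `U_a + U_b = n_a * n_b`.
#'
#' @param a,b Numeric samples, both nonempty.
#' @return List with `U` and two-sided `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  list(U = unname(u), p = unname(wt$p.value))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: reject all hypotheses up to
#' `k* = max(k : p_(k) <= k q / m)`; adjusted values are the standard
#' cumulative-minimum construction (as in [stats::p.adjust()], which is used
#' internally).
#'
#' @param pvals P-values in `[0, 1]` (NAs are carried through unrejected).
#' @param q_level Target average false discovery rate.
#' @return List with `q` (adjusted values) and `reject` (logical flags).
#' @export
bh_fdr <- function(pvals, q_level = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= q_level)
}

#' Empirical AUC of scores against binary labels
#'
#' Probability that a positive-class score exceeds a negative-class score,
#' ties counted one half: the Mann-Whitney statistic of the positive class
#' divided by `n1 * n0`.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    as.integer(labels == levels(labels)[2])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("labels must be binary")
    as.integer(labels)
  }
}

#' Bias-corrected and accelerated bootstrap CI for the AUC
#'
#' Resampling is stratified by class (each bootstrap sample keeps the group
#' sizes); the bias correction comes from the fraction of the bootstrap
#' distribution below the point estimate and the acceleration from the
#' jackknife skewness. If the bootstrap distribution is degenerate the
#' percentile interval is returned and flagged.
#'
#' @param scores,labels As in [empirical_auc()].
#' @param n_boot Number of bootstrap resamples (10,000 for reported
#'   intervals).
#' @param level Confidence level.
#' @param seed Integer seed (required for reproducible reported intervals).
#' @return List with `lower`, `upper`, `auc`, `method` (`"bca"` or
#'   `"percentile"`), `flagged`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 10000, level = 0.95,
                             seed = NULL) {
  y <- as_binary_labels(labels)
  i1 <- which(y == 1); i0 <- which(y == 0)
  n1 <- length(i1); n0 <- length(i0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (n1 + n0 < 5) stop("too few observations for a bootstrap interval")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  theta <- empirical_auc(scores, y)
  s1 <- scores[i1]; s0 <- scores[i0]
  boots <- vapply(seq_len(n_boot), function(b) {
    bs1 <- s1[sample.int(n1, n1, replace = TRUE)]
    bs0 <- s0[sample.int(n0, n0, replace = TRUE)]
    r <- rank(c(bs1, bs0))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  alpha <- (1 - level) / 2
  if (length(unique(boots)) == 1L) {
    q <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(list(lower = q[1], upper = q[2], auc = theta,
                method = "percentile", flagged = TRUE))
  }
  # bias correction: median bias of the bootstrap distribution
  frac <- (sum(boots < theta) + 0.5 * sum(boots == theta)) / n_boot
  frac <- min(max(frac, 1 / (2 * n_boot)), 1 - 1 / (2 * n_boot))
  z0 <- stats::qnorm(frac)
  # acceleration via the jackknife
  n <- n1 + n0
  jack <- vapply(seq_len(n), function(i) empirical_auc(scores[-i], y[-i]),
                 numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- sum((jm - jack)^2)
  a <- if (den > 0) num / (6 * den^1.5) else 0
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  q <- stats::quantile(boots, c(adj(zl), adj(zu)), names = FALSE, type = 6)
  list(lower = q[1], upper = q[2], auc = theta, method = "bca",
       flagged = FALSE)
}

# group membership for one contrast; returns list(ids_a, ids_b) with b the
# positive class (TBI, TBI+, CI+)
contrast_groups <- function(labels, contrast) {
  contrast <- match.arg(contrast, c("sham_tbi", "tbi_epilepsy", "ci"))
  switch(contrast,
    sham_tbi = list(a = labels$animal_id[labels$group == "sham"],
                    b = labels$animal_id[labels$group == "TBI"],
                    name_a = "sham", name_b = "TBI"),
    tbi_epilepsy = list(a = labels$animal_id[which(labels$epilepsy == FALSE)],
                        b = labels$animal_id[which(labels$epilepsy == TRUE)],
                        name_a = "TBI-", name_b = "TBI+"),
    ci = list(a = labels$animal_id[which(labels$cognition == FALSE)],
              b = labels$animal_id[which(labels$cognition == TRUE)],
              name_a = "CI-", name_b = "CI+"))
}

#' Position-wise group comparison of profile statistics
#'
#' For every cell (side, day, parameter, statistic in mean/SD, position),
#' compares the two groups of a contrast with the Mann-Whitney U test, and
#' controls the false discovery rate with Benjamini-Hochberg. By default one
#' BH family spans positions x parameters within each (side, day, statistic)
#' panel; `family = "global"` corrects across everything at once. Optionally
#' each cell also gets its single-parameter empirical AUC with a BCa
#' bootstrap CI.
#'
#' @param profiles Profile tibble in the [cohort_profiles()] layout.
#' @param labels Label tibble (animal_id, group, epilepsy, cognition).
#' @param contrast `"sham_tbi"`, `"tbi_epilepsy"` or `"ci"`.
#' @param q_level Target FDR.
#' @param family `"per_panel"` or `"global"`.
#' @param auc_ci Compute per-cell bootstrap AUC CIs (slower).
#' @param n_boot,seed Bootstrap settings for the per-cell CIs.
#' @return Tibble (`stat_grid`): side, day, parameter, statistic,
#'   position_mm, n_a, n_b, U, p, q, reject, auc and (optionally) auc_lo,
#'   auc_hi.
#' @export
profile_group_comparison <- function(profiles, labels, contrast,
                                     q_level = 0.05,
                                     family = c("per_panel", "global"),
                                     auc_ci = FALSE, n_boot = 10000,
                                     seed = NULL) {
  family <- match.arg(family)
  gr <- contrast_groups(labels, contrast)
  if (length(gr$a) < 2 || length(gr$b) < 2) {
    stop("need at least 2 animals per group")
  }
  long <- tidyr::pivot_longer(profiles, cols = c("wmean", "wsd"),
                              names_to = "statistic", values_to = "value")
  long$statistic <- ifelse(long$statistic == "wmean", "mean", "SD")
  long <- long[long$animal_id %in% c(gr$a, gr$b) & !is.na(long$value), ]
  # common position grid across animals within each cell
  cells <- dplyr::group_by(long, .data$side, .data$day, .data$parameter,
                           .data$statistic, .data$position_mm)
  res <- dplyr::summarise(
    cells,
    n_a = sum(.data$animal_id %in% gr$a),
    n_b = sum(.data$animal_id %in% gr$b),
    tst = list(mann_whitney_u(.data$value[.data$animal_id %in% gr$a],
                              .data$value[.data$animal_id %in% gr$b])),
    auc = empirical_auc(.data$value,
                        .data$animal_id %in% gr$b),
    .groups = "drop")
  res$U <- vapply(res$tst, `[[`, numeric(1), "U")
  res$p <- vapply(res$tst, `[[`, numeric(1), "p")
  res$tst <- NULL
  if (length(unique(res$n_a + res$n_b)) > 1) {
    stop("mismatched position grids across animals")
  }
  if (family == "global") {
    bh <- bh_fdr(res$p, q_level)
    res$q <- bh$q; res$reject <- bh$reject
  } else {
    res <- dplyr::group_by(res, .data$side, .data$day, .data$statistic)
    res <- dplyr::mutate(res, q = bh_fdr(.data$p, q_level)$q,
                         reject = bh_fdr(.data$p, q_level)$reject)
    res <- dplyr::ungroup(res)
  }
  if (auc_ci) {
    wide <- long
    cis <- mapply(function(sd_, dy, pa, st, po, i) {
      sub <- wide[wide$side == sd_ & wide$day == dy & wide$parameter == pa &
                    wide$statistic == st & wide$position_mm == po, ]
      ci <- bootstrap_auc_ci(sub$value, sub$animal_id %in% gr$b,
                             n_boot = n_boot,
                             seed = if (is.null(seed)) NULL else seed + i)
      c(ci$lower, ci$upper)
    }, res$side, res$day, res$parameter, res$statistic, res$position_mm,
    seq_len(nrow(res)))
    res$auc_lo <- cis[1, ]; res$auc_hi <- cis[2, ]
  }
  attr(res, "contrast") <- contrast
  attr(res, "groups") <- c(gr$name_a, gr$name_b)
  res
}
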