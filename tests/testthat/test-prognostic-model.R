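test_that("feature matrices follow the canonical 48-column layout", {
  cols <- feature_columns()
  expect_length(cols, 48)       # (2 params x 3 days + 9 params x 2 days) x 2
  expect_equal(cols[1:2], c("T2.D2.mean", "T2.D2.sd"))
  pr <- fake_profiles(6, positions = seq(0, 6, 1), seed = 8)
  X1 <- assemble_features(pr, 2, "ipsi")
  X3 <- assemble_features(pr, 3, "ipsi")
  expect_equal(dim(X1), c(6, 48))
  expect_identical(colnames(X1), colnames(X3))
  expect_identical(colnames(X1), cols)
  # an animal missing one cell is dropped with a message
  broken <- pr[!(pr$animal_id == "A002" & pr$parameter == "T2" &
                   pr$day == "D2" & pr$position_mm == 2), ]
  expect_message(Xb <- assemble_features(broken, 2, "ipsi"), "A002")
  expect_equal(nrow(Xb), 5)
  expect_false("A002" %in% rownames(Xb))
  pr3 <- fake_profiles(3, positions = c(0, 1), seed = 1)
  broken3 <- pr3[pr3$animal_id != "A001" | pr3$parameter != "T2", ]
  expect_error(suppressMessages(assemble_features(broken3, 1, "ipsi")),
               "fewer than 3")
})

test_that("class weights are inverse-frequency, normalized to n", {
  expect_equal(class_weights(rep(c(0, 1), each = 10)), rep(1, 20))
  w <- class_weights(rep(c(0, 1), c(16, 68)))
  expect_equal(sum(w), 84)
  expect_equal(unique(w[1:16]) / unique(w[17:84]), 68 / 16)
  y <- rep(c(0, 1), c(5, 9))
  o <- sample(14)
  expect_equal(class_weights(y[o]), class_weights(y)[o])
  expect_error(class_weights(rep(1, 8)), "both classes")
})

test_that("nested LOOCV detects separable data and flat data", {
  withr::local_seed(10)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 10 + stats::rnorm(n, 0, 0.1),
             matrix(stats::rnorm(n * 5), n))
  fit <- nested_loocv_elastic_net(X, y, inner = "loo")
  expect_equal(fit$auc, 1)
  # constant predictors: every out-of-fold probability is the weighted
  # training prevalence and the pooled AUC is 0.5
  Xc <- matrix(5, n, 4)
  fitc <- nested_loocv_elastic_net(Xc, y, inner = "loo")
  expect_true(all(abs(fitc$prob - 0.5) < 1e-12))
  expect_equal(fitc$auc, 0.5)
  expect_error(nested_loocv_elastic_net(X[1:4, ], y[1:4]), "at least 6")
  expect_error(nested_loocv_elastic_net(X, rep(c(0, 1), c(1, n - 1))),
               "per class")
})

test_that("pooled AUC is invariant to monotone transforms of probabilities", {
  withr::local_seed(12)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(y + stats::rnorm(20, 0, 1), matrix(stats::rnorm(40), 20))
  fit <- nested_loocv_elastic_net(X, y, inner = 3, nlambda = 20,
                                  lambda_min_ratio = 1e-2, seed = 3)
  expect_equal(empirical_auc(stats::qlogis(fit$prob), y), fit$auc)
  expect_equal(empirical_auc(fit$prob^3, y), fit$auc)
})

test_that("per-fold standardization differs from deliberate global leakage", {
  withr::local_seed(13)
  y <- rep(c(0, 1), each = 12)
  X <- matrix(stats::rnorm(24 * 8), 24, 8)
  X[, 1] <- X[, 1] + y * 1.5
  f_fold <- nested_loocv_elastic_net(X, y, inner = 3, nlambda = 20,
                                     lambda_min_ratio = 1e-2, seed = 5)
  f_glob <- nested_loocv_elastic_net(X, y, inner = 3, nlambda = 20,
                                     lambda_min_ratio = 1e-2, seed = 5,
                                     standardize = "global")
  expect_false(isTRUE(all.equal(f_fold$prob, f_glob$prob)))
})

test_that("determinism: same seed, same result", {
  withr::local_seed(14)
  y <- rep(c(0, 1), each = 10)
  X <- matrix(stats::rnorm(20 * 6), 20, 6)
  f1 <- nested_loocv_elastic_net(X, y, inner = 3, seed = 9, nlambda = 20,
                                 lambda_min_ratio = 1e-2)
  f2 <- nested_loocv_elastic_net(X, y, inner = 3, seed = 9, nlambda = 20,
                                 lambda_min_ratio = 1e-2)
  expect_identical(f1$prob, f2$prob)
  ci1 <- model_auc_with_ci(f1, n_boot = 400, seed = 21)
  ci2 <- model_auc_with_ci(f2, n_boot = 400, seed = 21)
  expect_identical(ci1, ci2)
})

test_that("coefficient importance averages folds and ranks predictors", {
  toy <- structure(list(coefs = matrix(c(1, 0, 0, 1), 2, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                        position = 3), class = "model_result")
  imp <- coefficient_importance(toy, k = 5)
  expect_equal(unname(sort(imp$avg_coef)), c(0.5, 0.5))
  zero <- structure(list(coefs = matrix(0, 3, 2,
                                        dimnames = list(NULL, c("a", "b"))),
                         position = 1), class = "model_result")
  impz <- coefficient_importance(zero)
  expect_equal(nrow(impz), 0)
  expect_true(attr(impz, "all_zero"))
  # an injected informative predictor ranks first
  withr::local_seed(15)
  y <- rep(c(0, 1), each = 15)
  X <- matrix(stats::rnorm(30 * 10), 30, 10,
              dimnames = list(NULL, paste0("v", 1:10)))
  X[, 4] <- X[, 4] + y * 2.5
  fit <- nested_loocv_elastic_net(X, y, inner = 3, nlambda = 20,
                                  lambda_min_ratio = 1e-2, seed = 2)
  expect_equal(coefficient_importance(fit, k = 3)$predictor[1], "v4")
})

test_that("volume models separate atrophy and stay flat without it", {
  withr::local_seed(16)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  base <- matrix(rep(c(38, 38, 38, 39, 39, 39), each = n), n, 6)
  colnames(base) <- paste(rep(c("ipsi", "contra"), each = 3),
                          c("D2", "D7", "D21"), sep = ".")
  noise <- matrix(stats::rnorm(n * 6, 0, 1), n, 6)
  vols <- base + noise
  vols[y == 1, 1:3] <- vols[y == 1, 1:3] * 0.8   # 20% ipsilateral atrophy
  fit <- volume_model(vols, y, inner = "loo")
  expect_gt(fit$auc, 0.9)
  flat <- volume_model(base + noise * 0, y, inner = "loo")
  expect_equal(flat$auc, 0.5)
  expect_error(volume_model(cbind(vols, NA), y), "incomplete")
})

test_that("position sweep flags positions by the CI-lower-bound rule", {
  lab <- fake_labels(n_sham = 5, n_tbi = 9, n_epi = 3, n_ci = 5, seed = 6)
  tbi_ids <- lab$animal_id[lab$group == "TBI"]
  shift_fun <- function(id, p, d, side, pos) {
    if (p == "T2" && side == "ipsi" && id %in% tbi_ids)
      8 * exp(-(pos - 3)^2 / 2) else 0
  }
  pr <- fake_profiles(14, positions = seq(1, 5, 1), sd_between = 1,
                      seed = 7, shift_fun = shift_fun)
  sw <- position_sweep(pr, lab, "sham_tbi", positions = c(1, 3, 5),
                       sides = "ipsi", n_boot = 300, seed = 4,
                       inner = 3, nlambda = 20, lambda_min_ratio = 1e-2)
  expect_equal(nrow(sw$summary), 3)
  expect_identical(sw$summary$flagged, sw$summary$auc_lo > 0.5)
  expect_true(sw$summary$flagged[sw$summary$position_mm == 3])
  # results carry per-position metadata for importance ranking
  imp <- coefficient_importance(sw$results, k = 5)
  expect_true("T2.D7.mean" %in% imp$predictor ||
                "T2.D2.mean" %in% imp$predictor ||
                "T2.D21.mean" %in% imp$predictor)
})
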