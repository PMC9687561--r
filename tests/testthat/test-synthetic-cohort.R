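test_that("rasterized tube volume approximates the analytic cylinder", {
  fx <- tube_fixture(radius = 1.5)
  vol <- mask_volume(fx$mask$indices, fx$grid)
  expect_lt(abs(vol - pi * 1.5^2 * 12) / (pi * 1.5^2 * 12), 0.05)
})

test_that("mask generation is deterministic and honours preconditions", {
  g <- voxel_grid(c(60, 60, 16))
  cl <- straight_centerline(c(1.5, 6, 4), c(1, 0, 0), 9)
  m1 <- generate_mask(g, cl, 1.2, seed = 3, jitter_sd = 0.05)
  m2 <- generate_mask(g, cl, 1.2, seed = 3, jitter_sd = 0.05)
  expect_identical(m1$indices, m2$indices)
  # curve exiting the grid is rejected
  out <- straight_centerline(c(2, 1, 4), c(1, 0, 0), 10)
  expect_error(generate_mask(g, out, 1.2), "exits")
  # unresolvably thin tube is rejected
  expect_error(generate_mask(g, cl, 0.3), "resolvable")
})

test_that("every mask voxel lies within the radius of the true centerline", {
  fx <- arc_fixture()
  mk <- fx$mask
  # independent check against a finer re-sampling of the analytic curve
  fine <- sample_centerline(fx$spec, step = 0.005)
  pts <- hippoaxis:::index_to_mm(mk$indices, fx$grid)
  pr <- hippoaxis:::project_points_to_polyline(pts, fine)
  half_diag <- sqrt(sum(fx$grid$vox_mm^2)) / 2
  expect_true(all(pr$dist <= fx$radius(pr$s) + half_diag))
})

test_that("parameter maps follow baseline + windowed effect + noise", {
  g <- voxel_grid(c(60, 60, 16))
  cl <- straight_centerline(c(1.5, 6, 4), c(1, 0, 0), 9)
  mk <- generate_mask(g, cl, 1.2)
  tbi <- list(id = "t", group = "TBI", epilepsy = FALSE, cognition = TRUE)
  sham <- list(id = "s", group = "sham")
  eff <- list(effect_spec("T2", "D7", "ipsi", "TBI", c(0, 3), amplitude = 10))
  zero_noise <- default_noise_sd() * 0
  m_tbi <- generate_parameter_maps(mk, tbi, "D7", "ipsi", eff,
                                   noise_sd = zero_noise,
                                   values_only = TRUE)
  m_sham <- generate_parameter_maps(mk, sham, "D7", "ipsi", eff,
                                    noise_sd = zero_noise,
                                    values_only = TRUE)
  base <- default_baselines()[["T2"]]
  s <- mk$proj$s
  # fully inside the window (clear of the 0.5-mm edge ramp)
  expect_equal(unname(m_tbi[s > 0.6 & s < 2.4, "T2"]),
               rep(base + 10, sum(s > 0.6 & s < 2.4)))
  expect_equal(unname(m_tbi[s > 3.1, "T2"]), rep(base, sum(s > 3.1)))
  # condition mismatch leaves sham untouched
  expect_equal(unname(m_sham[, "T2"]), rep(base, nrow(m_sham)))
  # no effects, zero noise: constant at baseline
  m0 <- generate_parameter_maps(mk, sham, "D7", "ipsi", list(),
                                noise_sd = zero_noise, values_only = TRUE)
  for (p in colnames(m0)) {
    expect_equal(unname(m0[, p]), rep(default_baselines()[[p]], nrow(m0)))
  }
  # two seeds differ only in the noise component
  mA <- generate_parameter_maps(mk, tbi, "D7", "ipsi", eff, seed = 1,
                                values_only = TRUE)
  mB <- generate_parameter_maps(mk, tbi, "D7", "ipsi", eff, seed = 2,
                                values_only = TRUE)
  expect_false(isTRUE(all.equal(mA, mB)))
  # both deviate from the shared deterministic part by zero-mean noise of
  # the configured SD
  for (m_ in list(mA, mB)) {
    resid <- m_[, "T2"] - m_tbi[, "T2"]
    expect_lt(abs(mean(resid)),
              5 * default_noise_sd()[["T2"]] / sqrt(nrow(m_)))
    expect_equal(stats::sd(resid), default_noise_sd()[["T2"]],
                 tolerance = 0.1)
  }
  # unknown parameter/day combinations are rejected
  bad <- list(effect_spec("FA", "D7", "ipsi", "TBI", c(0, 3), 1))
  bad[[1]]$day <- "D2"  # FA not acquired on D2
  expect_error(generate_parameter_maps(mk, tbi, "D2", "ipsi", bad), "not acquired")
})

test_that("echo series synthesis matches the closed-form decay", {
  s <- synthesize_echo_series(100, 50, echo_times = 50)
  expect_equal(as.numeric(s[1, 1, 1, 1]), 100 * exp(-1), tolerance = 1e-12)
  te <- c(0.01, 0.1, 1)
  s2 <- synthesize_echo_series(100, 50, te)
  expect_lt(abs(s2[1, 1, 1, 1] - 100), 0.05)   # TE -> 0 recovers S0
  expect_error(synthesize_echo_series(100, -3, echo_times = c(10, 20)),
               "relaxation")
  expect_error(synthesize_echo_series(100, 50, echo_times = c(20, 10)),
               "increasing")
  # Rician switch produces nonnegative magnitude signals
  r <- synthesize_echo_series(array(3, c(4, 4, 2)), 50, c(10, 30),
                              noise_sd = 5, seed = 1, rician = TRUE)
  expect_true(all(r >= 0))
  gsn <- synthesize_echo_series(array(3, c(4, 4, 2)), 50, c(10, 30),
                                noise_sd = 5, seed = 1, rician = FALSE)
  expect_true(any(gsn < 0))
})

test_that("echo synthesis and relaxometry round-trip at the spin-echo TE grid", {
  te <- seq(14.6, 87.6, length.out = 6)
  s0 <- array(120, c(6, 5, 4)); tt <- array(48, c(6, 5, 4))
  ser <- synthesize_echo_series(s0, tt, te)
  tmap <- fit_relaxation_map(ser, array(TRUE, c(6, 5, 4)))
  expect_lt(max(abs(tmap - 48)) / 48, 0.01)
})

test_that("DWI synthesis is rotationally consistent and round-trips", {
  pr <- dwi_protocol()
  expect_equal(nrow(pr$bvecs), 64)
  expect_equal(sum(pr$bvals == 0), 4)
  iso <- c(1, 1, 1, 0, 0, 0) * 1e-3
  sig <- synthesize_dwi(iso, pr$bvals, pr$bvecs, s0 = 100)
  dwis <- sig[1, pr$bvals > 0]
  expect_equal(unname(dwis), rep(100 * exp(-2), 60), tolerance = 1e-12)
  expect_equal(unname(sig[1, pr$bvals == 0]), rep(100, 4))
  # round trip
  D <- c(1.7, 0.3, 0.3, 0.1, -0.05, 0.02) * 1e-3
  s2 <- synthesize_dwi(D, pr$bvals, pr$bvecs)
  tf <- fit_tensor_loglinear(matrix(s2, 1), pr$bvals, pr$bvecs)
  expect_lt(max(abs(tf$tensors - rep(D, each = 1))), 1e-6 * 1e-3)
  # non-unit gradient rejected
  bv <- pr$bvecs; bv[10, ] <- bv[10, ] * 2
  expect_error(synthesize_dwi(D, pr$bvals, bv), "unit norm")
})

test_that("cohort labels follow deterministic prevalence rounding", {
  cfg <- small_cohort_config(n_sham = 3, n_tbi = 9, epilepsy_prev = 0.22,
                             ci_prev = 0.81, seed = 5)
  ch <- generate_cohort(cfg)
  lab <- cohort_labels(ch)
  expect_equal(nrow(lab), 12)
  expect_equal(sum(lab$epilepsy, na.rm = TRUE), round(0.22 * 9))
  expect_equal(sum(lab$cognition, na.rm = TRUE), round(0.81 * 9))
  expect_true(all(is.na(lab$epilepsy[lab$group == "sham"])))
  # zero prevalence: everyone negative
  ch0 <- generate_cohort(small_cohort_config(n_sham = 2, n_tbi = 6,
                                             epilepsy_prev = 0, ci_prev = 0,
                                             seed = 2))
  expect_true(all(!cohort_labels(ch0)$epilepsy, na.rm = TRUE))
  # prevalence without TBI animals is rejected
  expect_error(cohort_config(n_sham = 4, n_tbi = 0, epilepsy_prev = 0.5),
               "prevalence")
})

test_that("label assignment varies by seed while counts stay fixed", {
  counts <- t(sapply(1:15, function(s) {
    lab <- cohort_labels(generate_cohort(small_cohort_config(
      n_sham = 2, n_tbi = 10, epilepsy_prev = 0.3, ci_prev = 0.6, seed = s)))
    c(epi = sum(lab$epilepsy, na.rm = TRUE),
      ci = sum(lab$cognition, na.rm = TRUE),
      first_epi = which(lab$epilepsy)[1])
  }))
  expect_true(all(counts[, "epi"] == round(0.3 * 10)))
  expect_true(all(counts[, "ci"] == round(0.6 * 10)))
  expect_gt(length(unique(counts[, "first_epi"])), 1)  # assignment varies
})

test_that("cohort structure matches the acquisition design", {
  ch <- generate_cohort(small_cohort_config(n_sham = 2, n_tbi = 3, seed = 3))
  an <- ch$animals[[1]]
  for (side in c("ipsi", "contra")) {
    expect_setequal(names(an$sides[[side]]$maps), c("D2", "D7", "D21"))
    expect_setequal(colnames(an$sides[[side]]$maps$D2), c("T2", "T2star"))
    expect_setequal(colnames(an$sides[[side]]$maps$D7), map_parameters())
  }
  # determinism: identical config regenerates identical maps and labels
  ch2 <- generate_cohort(small_cohort_config(n_sham = 2, n_tbi = 3, seed = 3))
  expect_identical(cohort_labels(ch), cohort_labels(ch2))
  expect_identical(ch$animals[["A004"]]$sides$ipsi$maps$D7,
                   ch2$animals[["A004"]]$sides$ipsi$maps$D7)
})

test_that("effects stay confined to their arc-length window", {
  eff <- list(effect_spec("T2", "D7", "ipsi", "TBI", c(3, 6), amplitude = 8))
  # between-animal offsets are zeroed so the voxel-level two-sample test
  # targets the spatial confinement of the effect, not clustered animal
  # variability
  ch <- generate_cohort(small_cohort_config(n_sham = 6, n_tbi = 6,
                                            effects = eff, seed = 9,
                                            animal_sd = default_animal_sd() * 0))
  lab <- cohort_labels(ch)
  vals_out <- list(sham = c(), tbi = c())
  for (an in ch$animals) {
    sd_ <- an$sides$ipsi
    sel <- sd_$masks$D7
    s <- sd_$proj$s[sel]
    v <- sd_$maps$D7[, "T2"]
    outside <- s > 7.5 | s < 1.5     # window + ramp + smoothing margin
    key <- if (an$group == "sham") "sham" else "tbi"
    vals_out[[key]] <- c(vals_out[[key]], v[outside])
  }
  p <- stats::wilcox.test(vals_out$sham, vals_out$tbi)$p.value
  expect_gt(p, 0.001)
})
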