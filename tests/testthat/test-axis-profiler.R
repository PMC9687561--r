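test_that("straight-tube skeleton tracks the analytic axis", {
  fx <- tube_fixture(radius = 1.2)
  sk <- skeletonize_mask(fx$mask$mask, fx$grid)
  dev <- sqrt((sk$control_points[, 2] - fx$axis_y)^2 +
                (sk$control_points[, 3] - fx$axis_z)^2)
  expect_lt(max(dev), sqrt(sum(fx$grid$vox_mm^2)))   # within 1 voxel diagonal
  expect_lt(abs(sk$length - 12) / 12, 0.10)
  # interpolant arc length close to the control polyline length
  poly_len <- sum(sqrt(rowSums(diff(sk$control_points)^2)))
  expect_lt(abs(sk$length - poly_len) / poly_len, 0.05)
})

test_that("skeleton length is invariant to grid-axis orientation", {
  g <- voxel_grid(c(80, 80, 24))
  sk_x <- skeletonize_mask(
    generate_mask(g, straight_centerline(c(2, 8, 6), c(1, 0, 0), 12), 1.2)$mask, g)
  sk_y <- skeletonize_mask(
    generate_mask(g, straight_centerline(c(8, 2, 6), c(0, 1, 0), 12), 1.2)$mask, g)
  expect_lt(abs(sk_x$length - sk_y$length), 0.6)
})

test_that("degenerate masks are rejected with clear messages", {
  g <- voxel_grid(c(40, 40, 12))
  expect_error(skeletonize_mask(array(FALSE, g$shape), g), "empty")
  two <- array(FALSE, g$shape)
  two[5:10, 5:10, 3:5] <- TRUE
  two[30:35, 30:35, 8:10] <- TRUE
  expect_error(skeletonize_mask(two, g), "disconnected")
  one <- array(FALSE, g$shape); one[20, 20, 6] <- TRUE
  expect_error(skeletonize_mask(one, g), "small|short|tube")
})

test_that("a closed-loop (ring) mask is rejected", {
  g <- voxel_grid(c(80, 80, 12))
  ctr <- c(8, 8, 3)
  ijk <- as.matrix(expand.grid(1:80, 1:80, 1:12))
  mm <- sweep((ijk - 0.5), 2, g$vox_mm, `*`)
  inplane <- sqrt((mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2)
  ring <- abs(inplane - 5) <= 1.2 & abs(mm[, 3] - ctr[3]) <= 1.2
  mask <- array(FALSE, g$shape); mask[ring] <- TRUE
  expect_error(skeletonize_mask(mask, g), "loop|ring")
})

test_that("temporal end orientation follows the hint", {
  fx <- arc_fixture()
  start_true <- fx$mask$centerline$points[1, ]
  end_true <- fx$mask$centerline$points[nrow(fx$mask$centerline$points), ]
  sk1 <- skeletonize_mask(fx$mask$mask, fx$grid, temporal_hint = start_true)
  sk2 <- skeletonize_mask(fx$mask$mask, fx$grid, temporal_hint = end_true)
  d11 <- sum((sk1$control_points[1, ] - start_true)^2)
  d21 <- sum((sk2$control_points[1, ] - end_true)^2)
  expect_lt(d11, 1.5^2)
  expect_lt(d21, 1.5^2)
})

test_that("projection onto a straight axis recovers axial coordinates", {
  fx <- tube_fixture(radius = 1.2)
  # exact axis as the skeleton: the closed-form projection is s = x - x0
  sk <- hippoaxis:::build_skeleton(cbind(seq(2, 14, 1), fx$axis_y, fx$axis_z))
  pv <- project_voxels(fx$mask$mask, fx$grid, sk)
  centers <- hippoaxis:::index_to_mm(pv$index, fx$grid)
  expect_lt(max(abs(pv$s - pmin(pmax(centers[, 1] - 2, 0), 12))), 0.05)
  # a control point is on the curve: its own projection has s equal to the
  # control arc length and distance 0
  cp <- hippoaxis:::project_points_to_polyline(
    sk$control_points[5, , drop = FALSE], sk$dense)
  expect_equal(cp$s, sk$control_s[5], tolerance = 0.01)
  expect_lt(cp$dist, 1e-6)
})

test_that("projection agrees with an exhaustive fine-sampled oracle", {
  fx <- arc_fixture()
  sk <- skeletonize_mask(fx$mask$mask, fx$grid)
  pv <- project_voxels(fx$mask$mask, fx$grid, sk)
  withr::local_seed(77)
  pick <- sample(length(pv$index), 1000)
  pts <- hippoaxis:::index_to_mm(pv$index[pick], fx$grid)
  # independent oracle: re-evaluate the interpolant at 0.001-mm resolution
  u <- sk$control_s
  uu <- seq(0, max(u), by = 0.001)
  fine <- cbind(pracma::pchip(u, sk$control_points[, 1], uu),
                pracma::pchip(u, sk$control_points[, 2], uu),
                pracma::pchip(u, sk$control_points[, 3], uu))
  ds <- sqrt(rowSums(diff(fine)^2))
  s_fine <- c(0, cumsum(ds))
  pr <- hippoaxis:::project_points_to_polyline(
    pts, list(points = fine, s = s_fine))
  expect_lt(max(abs(pv$s[pick] - pr$s)), 0.01)
})

test_that("weighted profiles match their defining formulas", {
  withr::local_seed(123)
  s <- stats::runif(200, 0, 12)
  x <- stats::rnorm(200, 50, 4)
  positions <- seq(0.5, 11.5, 0.5)
  prof <- weighted_profile(x, list(s = s), positions, fwhm = 1.5)
  # independent direct-summation implementation of the same estimator
  sigma <- 1.5 / sqrt(8 * log(2))
  for (k in seq_along(positions)) {
    p <- positions[k]
    w <- ifelse(abs(s - p) <= 4 * sigma,
                exp(-(s - p)^2 / (2 * sigma^2)), 0)
    m <- 0; v <- 0
    for (i in seq_along(x)) m <- m + w[i] * x[i]
    m <- m / sum(w)
    for (i in seq_along(x)) v <- v + w[i] * (x[i] - m)^2
    v <- v / sum(w)
    expect_equal(prof$wmean[k], m, tolerance = 1e-10)
    expect_equal(prof$wsd[k], sqrt(v), tolerance = 1e-10)
  }
})

test_that("profile limits behave: constant fields, symmetry, tiny fwhm", {
  s <- seq(0, 10, 0.05)
  const <- weighted_profile(rep(7, length(s)), list(s = s), seq(1, 9, 1))
  expect_true(all(const$wmean == 7))
  expect_true(all(const$wsd == 0))
  # linear field: interior mean equals the position
  lin <- weighted_profile(s, list(s = s), seq(2, 8, 1))
  expect_lt(max(abs(lin$wmean - seq(2, 8, 1))), 0.02)
  # fwhm -> 0 picks out the nearest voxel value
  x <- stats::rnorm(length(s))
  tiny <- weighted_profile(x, list(s = s), c(2, 5), fwhm = 0.02)
  expect_equal(tiny$wmean[1], x[which.min(abs(s - 2))], tolerance = 1e-6)
  # voxel enumeration order does not matter
  o <- sample(length(s))
  perm <- weighted_profile(x[o], list(s = s[o]), seq(1, 9, 1))
  ref <- weighted_profile(x, list(s = s), seq(1, 9, 1))
  expect_equal(perm$wmean, ref$wmean, tolerance = 1e-12)
  # unsupported positions are NA-flagged
  far <- weighted_profile(x, list(s = s), c(5, 50))
  expect_true(is.na(far$wmean[2]))
  expect_error(weighted_profile(x, list(s = s), c(5, 4)), "increasing")
})

test_that("surface exclusion is a 6-connected erosion", {
  fx <- tube_fixture(radius = 1.2)
  interior <- exclude_surface(fx$mask$mask)
  expect_true(all(fx$mask$mask[interior]))        # containment
  expect_lt(sum(interior), sum(fx$mask$mask))
  # independent brute-force oracle on random blobs
  withr::local_seed(9)
  for (rep in 1:3) {
    m <- array(stats::runif(6 * 6 * 5) > 0.4, c(6, 6, 5))
    m[2:4, 2:4, 2:3] <- TRUE                      # guarantee an interior
    ref <- array(FALSE, dim(m))
    for (i in 2:5) for (j in 2:5) for (k in 2:4) {
      ref[i, j, k] <- m[i, j, k] && m[i - 1, j, k] && m[i + 1, j, k] &&
        m[i, j - 1, k] && m[i, j + 1, k] && m[i, j, k - 1] && m[i, j, k + 1]
    }
    expect_identical(exclude_surface(m), ref)
  }
  # erosion of a 6-connectivity digital ball shrinks its radius by one
  ball <- array(FALSE, c(11, 11, 11))
  ctr <- c(6, 6, 6); r <- 4
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    ball[i, j, k] <- sum(abs(c(i, j, k) - ctr)) <= r
  }
  er <- exclude_surface(ball)
  ref <- array(FALSE, c(11, 11, 11))
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    ref[i, j, k] <- sum(abs(c(i, j, k) - ctr)) <= r - 1
  }
  expect_identical(er, ref)
  expect_error(exclude_surface(array(FALSE, c(3, 3, 3))), "empty")
  single <- array(FALSE, c(3, 3, 3)); single[2, 2, 2] <- TRUE
  expect_error(exclude_surface(single), "empties")
})

test_that("mask volume is count times voxel volume", {
  g <- voxel_grid(c(20, 20, 10), c(0.15, 0.15, 0.5))
  expect_equal(mask_volume(array(FALSE, g$shape), g), 0)
  m <- array(FALSE, g$shape); m[sample(prod(g$shape), 1000)] <- TRUE
  expect_equal(mask_volume(m, g), 1000 * 0.15 * 0.15 * 0.5)
})

test_that("an injected effect appears in profiles where it was placed", {
  eff <- list(effect_spec("T2", "D7", "ipsi", "TBI", c(3, 6), amplitude = 10))
  ch <- generate_cohort(small_cohort_config(
    n_sham = 4, n_tbi = 4, effects = eff, seed = 31,
    animal_sd = default_animal_sd() * 0))
  pr <- cohort_profiles(ch, projection = "truth", positions = seq(0, 12, 0.5))
  lab <- cohort_labels(ch)
  sub <- pr[pr$parameter == "T2" & pr$day == "D7" & pr$side == "ipsi", ]
  diff_at <- sapply(split(sub, sub$position_mm), function(d) {
    mean(d$wmean[d$animal_id %in% lab$animal_id[lab$group == "TBI"]]) -
      mean(d$wmean[d$animal_id %in% lab$animal_id[lab$group == "sham"]])
  })
  pos <- as.numeric(names(diff_at))
  expect_gt(min(diff_at[pos > 3.6 & pos < 5.4]), 7)      # inside the window
  expect_lt(max(abs(diff_at[pos < 3 - 2 * 1.5 | pos > 6 + 2 * 1.5])), 1)
})
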