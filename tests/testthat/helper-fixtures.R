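# Shared fixtures, all generated in code at test time.

# coarse test grid that still fits the default two-sided geometry
coarse_grid <- function() voxel_grid(c(56, 56, 12), c(0.35, 0.35, 1.0))

# straight tube mask on a mid-resolution grid
tube_fixture <- function(radius = 1.2, length_mm = 12,
                         grid = voxel_grid(c(80, 80, 24))) {
  cl <- straight_centerline(c(2, 8, 6), c(1, 0, 0), length_mm)
  list(grid = grid, centerline = cl,
       mask = generate_mask(grid, cl, radius), radius = radius,
       axis_y = 8, axis_z = 6)
}

# curved arc mask with tapering radius (the default cohort geometry)
arc_fixture <- function(grid = voxel_grid(c(90, 90, 24)), axis_len = 12,
                        side = "ipsi") {
  spec <- hippoaxis:::default_side_geometry(grid, axis_len, side)
  rad <- hippoaxis:::default_radius_profile(axis_len)
  list(grid = grid, spec = spec, radius = rad,
       mask = generate_mask(grid, spec, rad))
}

# small fast cohort config; no effects unless supplied
small_cohort_config <- function(n_sham = 4, n_tbi = 8, effects = list(),
                                epilepsy_prev = 0.5, ci_prev = 0.5,
                                seed = 1, geometry_jitter = 0,
                                atrophy = no_atrophy(), ...) {
  cohort_config(n_sham = n_sham, n_tbi = n_tbi,
                epilepsy_prev = epilepsy_prev, ci_prev = ci_prev,
                grid = coarse_grid(), axis_len = 12, effects = effects,
                geometry_jitter = geometry_jitter, atrophy = atrophy,
                seed = seed, ...)
}

no_atrophy <- function() {
  list(ipsi = c(D2 = 1, D7 = 1, D21 = 1), contra = c(D2 = 1, D7 = 1, D21 = 1))
}

# synthetic profile tibble drawn directly at the profile level (fast path for
# statistics tests that do not need images)
fake_profiles <- function(n_animals, positions = seq(0, 12, 1), sd_between = 1,
                          seed = 1, shift_fun = NULL) {
  withr::local_seed(seed)
  ids <- sprintf("A%03d", seq_len(n_animals))
  rows <- list()
  for (p in map_parameters()) {
    for (d in map_days(p)) {
      for (side in c("ipsi", "contra")) {
        base <- default_baselines()[[p]]
        for (a in seq_len(n_animals)) {
          off <- stats::rnorm(1, 0, sd_between)
          wm <- base + off + stats::rnorm(length(positions), 0, 0.1 * sd_between)
          if (!is.null(shift_fun)) {
            wm <- wm + shift_fun(ids[a], p, d, side, positions)
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            animal_id = ids[a], side = side, day = d, parameter = p,
            position_mm = positions, wmean = wm,
            wsd = abs(stats::rnorm(length(positions), 1, 0.1 * sd_between)),
            n_eff = 50)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

fake_labels <- function(n_sham, n_tbi, n_epi, n_ci, seed = 1) {
  withr::local_seed(seed)
  n <- n_sham + n_tbi
  ids <- sprintf("A%03d", seq_len(n))
  group <- rep(c("sham", "TBI"), c(n_sham, n_tbi))
  epi <- cog <- rep(NA, n)
  tbi <- which(group == "TBI")
  epi[tbi] <- FALSE; cog[tbi] <- FALSE
  epi[sample(tbi, n_epi)] <- TRUE
  cog[sample(tbi, n_ci)] <- TRUE
  tibble::tibble(animal_id = ids, group = group, epilepsy = epi,
                 cognition = cog)
}
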