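#' Synthetic hippocampus mask on a voxel grid
#'
#' Rasterizes a curved tube around an analytic centerline: a voxel belongs to
#' the mask when its centre lies within `radius_profile(s)` of the curve,
#' where `s` is the arc length of the nearest point on the curve. The analytic
#' centerline and the per-voxel projection are returned alongside the mask so
#' that downstream skeleton and projection code can be validated against an
#' exact oracle.
#'
#' @param grid A [voxel_grid()].
#' @param centerline A `centerline_spec` from [straight_centerline()] or
#'   [arc_centerline()].
#' @param radius_profile Either a single radius (mm) or a function of arc
#'   length `s` returning the local tube radius (mm).
#' @param seed Optional integer seed controlling the (optional) smooth radius
#'   jitter; with `jitter_sd = 0` the mask is deterministic regardless.
#' @param jitter_sd Relative SD of a smooth multiplicative perturbation of the
#'   radius along the axis (0 disables).
#' @param step Centerline sampling step (mm) used for rasterization and the
#'   returned oracle polyline.
#' @return A `hippo_mask` list: `mask` (logical 3D array), `indices` (linear
#'   indices of in-mask voxels), `proj` (`s`, `dist` for in-mask voxel
#'   centres, against the true centerline), `centerline` (dense polyline with
#'   `points`, `s`), `radius` (radius at the polyline samples), `grid`.
#' @export
generate_mask <- function(grid, centerline, radius_profile, seed = NULL,
                          jitter_sd = 0, step = 0.02) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(centerline, "centerline_spec"))
  rfun <- if (is.function(radius_profile)) radius_profile else {
    r0 <- as.numeric(radius_profile); function(s) rep(r0, length(s))
  }
  poly <- sample_centerline(centerline, step = step)
  radius <- rfun(poly$s)
  if (length(radius) == 1L) radius <- rep(radius, length(poly$s))
  if (any(!is.finite(radius)) || any(radius <= 0)) {
    stop("radius profile must be finite and positive")
  }
  if (min(radius) < 2 * max(grid$vox_mm[1:2])) {
    stop("tube radius below resolvable size (< 2 in-plane voxels)")
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) withr::local_seed(as.integer(seed))
    # smooth low-order perturbation of the radius along the axis
    L <- max(poly$s)
    amp <- stats::rnorm(3, 0, jitter_sd / sqrt(3))
    pha <- stats::runif(3, 0, 2 * pi)
    mod <- 1 + amp[1] * cos(pi * poly$s / L + pha[1]) +
      amp[2] * cos(2 * pi * poly$s / L + pha[2]) +
      amp[3] * cos(3 * pi * poly$s / L + pha[3])
    radius <- radius * pmax(mod, 0.5)
  }
  rmax <- max(radius)
  ext <- grid_extent(grid)
  lo <- apply(poly$points, 2, min); hi <- apply(poly$points, 2, max)
  if (any(lo - rmax < 0) || any(hi + rmax > ext)) {
    stop("centerline (plus maximum radius) exits the voxel grid")
  }
  # candidate voxels from the tube bounding box only
  diag_half <- sqrt(sum(grid$vox_mm^2)) / 2
  lo_ijk <- pmax(floor((lo - rmax - diag_half) / grid$vox_mm) + 1L, 1L)
  hi_ijk <- pmin(ceiling((hi + rmax + diag_half) / grid$vox_mm), grid$shape)
  cand_ijk <- as.matrix(expand.grid(i = lo_ijk[1]:hi_ijk[1],
                                    j = lo_ijk[2]:hi_ijk[2],
                                    k = lo_ijk[3]:hi_ijk[3]))
  cand_idx <- ijk_to_index(cand_ijk, grid)
  pts_mm <- ijk_to_mm(cand_ijk, grid)
  pr <- project_points_to_polyline(pts_mm, poly)
  rad_at <- radius[match(pr$s, poly$s)]
  inside <- pr$dist <= rad_at
  # flat end caps: points projecting onto a curve endpoint are kept only if
  # they do not overhang the end plane; their radial (perpendicular)
  # distance replaces the Euclidean one
  np <- nrow(poly$points)
  for (end in c(1L, np)) {
    hit <- which(pr$s == poly$s[end])
    if (!length(hit)) next
    tangent <- if (end == 1L) poly$points[2, ] - poly$points[1, ] else
      poly$points[np, ] - poly$points[np - 1L, ]
    tangent <- tangent / sqrt(sum(tangent^2))
    rel <- pts_mm[hit, , drop = FALSE] -
      rep(poly$points[end, ], each = length(hit))
    over <- as.numeric(rel %*% tangent)
    if (end == 1L) over <- -over
    radial <- sqrt(pmax(rowSums(rel^2) - over^2, 0))
    ok <- over <= step / 2 & radial <= rad_at[hit]
    inside[hit] <- ok
    pr$dist[hit] <- radial
  }
  idx <- cand_idx[inside]
  structure(list(
    mask = indices_to_array(idx, grid),
    indices = idx,
    proj = list(s = pr$s[inside], dist = pr$dist[inside]),
    centerline = poly,
    radius = radius,
    grid = grid
  ), class = "hippo_mask")
}

#' Effect specification for the synthetic cohort
#'
#' Describes one localized group effect: for animals matching `condition`,
#' the named parameter map on the given day and side is shifted by
#' `amplitude` (additive, parameter units) inside the arc-length window, with
#' 0.5-mm half-cosine edge ramps, and/or its voxel noise is scaled by
#' `sd_scale` inside the window.
#'
#' @param parameter Parameter name (e.g. `"T2"`, `"FA"`).
#' @param day Day label: `"D2"`, `"D7"` or `"D21"`.
#' @param side `"ipsi"` or `"contra"`.
#' @param condition Group condition: one of `"TBI"`, `"sham"`, `"TBI+"`,
#'   `"TBI-"`, `"CI+"`, `"CI-"`.
#' @param window Length-2 numeric, arc-length window in mm from the temporal
#'   end.
#' @param amplitude Additive shift in parameter units (default 0).
#' @param sd_scale Multiplier on the voxel noise SD inside the window
#'   (default 1).
#' @export
effect_spec <- function(parameter, day, side, condition, window,
                        amplitude = 0, sd_scale = 1) {
  stopifnot(length(window) == 2, window[1] <= window[2], is.finite(amplitude))
  day <- match.arg(day, c("D2", "D7", "D21"))
  side <- match.arg(side, c("ipsi", "contra"))
  condition <- match.arg(condition, c("TBI", "sham", "TBI+", "TBI-", "CI+", "CI-"))
  structure(list(parameter = parameter, day = day, side = side,
                 condition = condition, window = as.numeric(window),
                 amplitude = amplitude, sd_scale = sd_scale),
            class = "effect_spec")
}

#' Canonical parameter set and acquisition days
#'
#' Relaxation parameters (T2, T2*) are imaged on D2, D7 and D21; diffusion
#' parameters on D7 and D21 only (no diffusion acquisition at the earliest
#' timepoint).
#' @return Character vector of parameter names, or day labels for one
#'   parameter.
#' @export
map_parameters <- function() {
  c("T2", "T2star", "FA", "MD", "RD",
    "lambda1", "lambda2", "lambda3", "cl", "cp", "cs")
}

#' @rdname map_parameters
#' @param parameter Parameter name.
#' @export
map_days <- function(parameter) {
  if (parameter %in% c("T2", "T2star")) c("D2", "D7", "D21") else c("D7", "D21")
}

#' Rodent-plausible baseline values and noise levels
#'
#' These defaults are generator knobs in physiologically plausible ranges for
#' rat hippocampus at high field (T2 about 55 ms, MD about 0.7e-3 mm^2/s,
#' FA about 0.25); they are deliberately round numbers, not measurements.
#' `default_noise_sd` is the voxel-level map noise; `default_animal_sd` the
#' between-animal biological variation (a per-animal offset constant across
#' the map).
#' @return Named numeric vector over [map_parameters()].
#' @export
default_baselines <- function() {
  c(T2 = 55, T2star = 40, FA = 0.25, MD = 0.7e-3, RD = 0.6e-3,
    lambda1 = 0.9e-3, lambda2 = 0.65e-3, lambda3 = 0.55e-3,
    cl = 0.12, cp = 0.095, cs = 0.785)
}

#' @rdname default_baselines
#' @export
default_noise_sd <- function() {
  c(T2 = 2, T2star = 2, FA = 0.02, MD = 0.04e-3, RD = 0.04e-3,
    lambda1 = 0.04e-3, lambda2 = 0.04e-3, lambda3 = 0.04e-3,
    cl = 0.02, cp = 0.02, cs = 0.02)
}

#' @rdname default_baselines
#' @export
default_animal_sd <- function() {
  c(T2 = 1.5, T2star = 1.5, FA = 0.015, MD = 0.03e-3, RD = 0.03e-3,
    lambda1 = 0.03e-3, lambda2 = 0.03e-3, lambda3 = 0.03e-3,
    cl = 0.015, cp = 0.015, cs = 0.015)
}

#' Default injected group effects
#'
#' Emulates the qualitative injury pattern along the septotemporal axis
#' (position 0 = temporal end, `axis_len` = septal end): early vasogenic
#' T2/T2* increase throughout the ipsilateral hippocampus, later septal T2
#' decrease, transient D7 MD increase, septal FA loss with a shift from
#' linear towards planar/spherical tensor shape, and milder septal changes
#' contralaterally. Cognitive impairment carries a moderate contralateral
#' mid-axis signature; epilepsy carries no injected effect at all, so that
#' contrast is a true null. Amplitudes are generator knobs chosen relative to
#' the between-animal SD, not measured values.
#'
#' @param axis_len Axis length in mm.
#' @return List of [effect_spec()] objects.
#' @export
default_effects <- function(axis_len = 12) {
  L <- axis_len
  list(
    # sham vs TBI, ipsilateral
    effect_spec("T2", "D2", "ipsi", "TBI", c(0, L), amplitude = 8),
    effect_spec("T2star", "D2", "ipsi", "TBI", c(0, L), amplitude = 6),
    effect_spec("T2", "D7", "ipsi", "TBI", c(L - 5, L), amplitude = -5),
    effect_spec("T2", "D21", "ipsi", "TBI", c(3, L), amplitude = -5),
    effect_spec("T2star", "D21", "ipsi", "TBI", c(3, L), amplitude = -4),
    effect_spec("MD", "D7", "ipsi", "TBI", c(0, L), amplitude = 0.12e-3),
    effect_spec("FA", "D7", "ipsi", "TBI", c(L - 5, L - 1), amplitude = -0.06,
                sd_scale = 1.4),
    effect_spec("cl", "D21", "ipsi", "TBI", c(L - 4, L), amplitude = -0.05),
    effect_spec("cp", "D21", "ipsi", "TBI", c(L - 4, L), amplitude = 0.05),
    # sham vs TBI, contralateral (milder, septal)
    effect_spec("T2", "D2", "contra", "TBI", c(0, L), amplitude = 3),
    effect_spec("T2star", "D2", "contra", "TBI", c(0, L), amplitude = 2.5),
    effect_spec("T2", "D7", "contra", "TBI", c(L - 4, L), amplitude = -2.5),
    effect_spec("FA", "D21", "contra", "TBI", c(L - 4, L), amplitude = -0.04),
    effect_spec("cl", "D21", "contra", "TBI", c(L - 4, L), amplitude = -0.03),
    effect_spec("cs", "D21", "contra", "TBI", c(L - 4, L), amplitude = 0.04),
    # cognitive impairment: moderate contralateral mid-axis signature
    effect_spec("cp", "D7", "contra", "CI+", c(3, 6), amplitude = 0.02),
    effect_spec("MD", "D7", "contra", "CI+", c(3, 6), amplitude = 0.035e-3),
    effect_spec("T2", "D2", "contra", "CI+", c(3, 6), amplitude = 1.5)
    # epilepsy: intentionally no effect (null contrast)
  )
}

#' Cohort configuration
#'
#' @param n_sham,n_tbi Group sizes (defaults mirror the study composition:
#'   16 sham, 68 TBI).
#' @param epilepsy_prev,ci_prev Prevalence of post-traumatic epilepsy and of
#'   cognitive impairment among TBI animals (defaults 0.22 and 0.81).
#' @param grid [voxel_grid()] the cohort is rasterized on.
#' @param axis_len Hippocampus axis length (mm).
#' @param effects List of [effect_spec()]s; see [default_effects()].
#' @param baselines,noise_sd,animal_sd Named numeric vectors over
#'   [map_parameters()].
#' @param atrophy Named list `ipsi`/`contra`, each a named numeric vector of
#'   TBI radius-scale factors per day (values in (0, 1]); sham animals keep
#'   scale 1. Models progressive ipsilateral volume loss.
#' @param geometry_jitter Scale of the per-animal geometric perturbation
#'   (translation in mm; 0 gives identical geometry across animals).
#' @param seed Master seed; a fixed config (including seed) regenerates the
#'   cohort exactly.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_sham = 16, n_tbi = 68,
                          epilepsy_prev = 0.22, ci_prev = 0.81,
                          grid = voxel_grid(c(90, 90, 24)),
                          axis_len = 12,
                          effects = default_effects(axis_len),
                          baselines = default_baselines(),
                          noise_sd = default_noise_sd(),
                          animal_sd = default_animal_sd(),
                          atrophy = list(
                            ipsi = c(D2 = 0.97, D7 = 0.93, D21 = 0.88),
                            contra = c(D2 = 1, D7 = 1, D21 = 1)),
                          geometry_jitter = 0.15,
                          seed = 1) {
  stopifnot(n_sham >= 0, n_tbi >= 0,
            epilepsy_prev >= 0, epilepsy_prev <= 1,
            ci_prev >= 0, ci_prev <= 1)
  if (n_tbi == 0 && (epilepsy_prev > 0 || ci_prev > 0)) {
    stop("nonzero prevalence requires TBI animals")
  }
  for (e in effects) {
    if (!e$parameter %in% map_parameters()) {
      stop("effect references unknown parameter: ", e$parameter)
    }
    if (!e$day %in% map_days(e$parameter)) {
      stop("effect references day ", e$day, " on which ", e$parameter,
           " is not acquired")
    }
    if (e$window[1] < 0 || e$window[2] > axis_len) {
      stop("effect window outside [0, axis length]")
    }
  }
  structure(list(n_sham = n_sham, n_tbi = n_tbi,
                 epilepsy_prev = epilepsy_prev, ci_prev = ci_prev,
                 grid = grid, axis_len = axis_len, effects = effects,
                 baselines = baselines, noise_sd = noise_sd,
                 animal_sd = animal_sd, atrophy = atrophy,
                 geometry_jitter = geometry_jitter,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Does this animal match an effect condition?
matches_condition <- function(animal, condition) {
  switch(condition,
    "TBI"  = animal$group == "TBI",
    "sham" = animal$group == "sham",
    "TBI+" = isTRUE(animal$epilepsy),
    "TBI-" = animal$group == "TBI" && !isTRUE(animal$epilepsy),
    "CI+"  = isTRUE(animal$cognition),
    "CI-"  = animal$group == "TBI" && !isTRUE(animal$cognition),
    stop("unknown condition: ", condition))
}

# 0.5-mm half-cosine ramp weight for an arc-length window
window_weight <- function(s, window, ramp = 0.5) {
  up <- pmin(pmax((s - window[1]) / ramp, 0), 1)
  dn <- pmin(pmax((window[2] - s) / ramp, 0), 1)
  0.25 * (1 - cospi(up)) * (1 - cospi(dn))
}

#' Generate quantitative parameter maps for one animal/day
#'
#' Per-voxel value = baseline + sum of applicable windowed effect amplitudes
#' (smooth half-cosine edges, evaluated at the true arc length of each voxel)
#' + a per-animal offset + Gaussian voxel noise. Effects apply only when the
#' animal matches the effect condition and the effect names this day/side.
#'
#' @param mask A `hippo_mask` from [generate_mask()] (supplies the analytic
#'   arc-length projection).
#' @param animal A list with `group` and optional `epilepsy`/`cognition`
#'   logical labels (see [generate_cohort()]).
#' @param day Day label.
#' @param side Side label the mask represents (`"ipsi"`/`"contra"`).
#' @param effects List of [effect_spec()].
#' @param baselines,noise_sd Named numeric vectors (parameter units).
#' @param animal_offset Optional named numeric vector of per-animal offsets
#'   (defaults to 0).
#' @param parameters Which parameters to generate (defaults to all acquired
#'   on `day`).
#' @param seed Optional seed for the noise.
#' @param values_only If `TRUE` return a matrix of in-mask voxel values
#'   (voxels x parameters) instead of full 3D arrays.
#' @return Named list of 3D `parameter_map` arrays (NA outside the mask) or,
#'   with `values_only = TRUE`, a numeric matrix.
#' @export
generate_parameter_maps <- function(mask, animal, day, side = "ipsi",
                                    effects = list(),
                                    baselines = default_baselines(),
                                    noise_sd = default_noise_sd(),
                                    animal_offset = NULL,
                                    parameters = NULL, seed = NULL,
                                    values_only = FALSE) {
  stopifnot(inherits(mask, "hippo_mask"))
  day <- match.arg(day, c("D2", "D7", "D21"))
  if (is.null(parameters)) {
    parameters <- map_parameters()[vapply(map_parameters(),
                                          function(p) day %in% map_days(p),
                                          logical(1))]
  }
  for (e in effects) {
    if (!e$parameter %in% map_parameters()) {
      stop("effect references unknown parameter: ", e$parameter)
    }
    if (!e$day %in% map_days(e$parameter)) {
      stop("effect references day ", e$day, " on which ", e$parameter,
           " is not acquired")
    }
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  s <- mask$proj$s
  nvox <- length(mask$indices)
  out <- matrix(NA_real_, nvox, length(parameters),
                dimnames = list(NULL, parameters))
  for (p in parameters) {
    base <- baselines[[p]]
    if (is.null(base) || base <= 0 && p %in% c("T2", "T2star")) {
      stop("baseline for ", p, " must be physiologically positive")
    }
    val <- rep(base, nvox)
    sdv <- rep(noise_sd[[p]], nvox)
    for (e in effects) {
      if (e$parameter != p || e$day != day || e$side != side) next
      if (!matches_condition(animal, e$condition)) next
      w <- window_weight(s, e$window)
      val <- val + e$amplitude * w
      if (e$sd_scale != 1) sdv <- sdv * (1 + (e$sd_scale - 1) * w)
    }
    off <- if (!is.null(animal_offset)) animal_offset[[p]] else 0
    if (is.null(off) || is.na(off)) off <- 0
    out[, p] <- val + off + stats::rnorm(nvox, 0, sdv)
  }
  if (values_only) return(out)
  lapply(stats::setNames(parameters, parameters), function(p) {
    a <- array(NA_real_, dim = mask$grid$shape)
    a[mask$indices] <- out[, p]
    structure(a, grid = mask$grid, parameter = p, day = day, side = side,
              class = c("parameter_map", "array"))
  })
}

#' Synthesize a multi-echo series from S0 and relaxation-time maps
#'
#' Monoexponential decay: `signal(TE) = S0 * exp(-TE / T) + noise` per voxel.
#'
#' @param s0 3D array (or scalar) of signal at zero echo time.
#' @param relax 3D array (or scalar) of relaxation times (ms); must be
#'   positive wherever `mask` is `TRUE`.
#' @param echo_times Strictly increasing positive echo times (ms).
#' @param noise_sd Gaussian noise SD (same units as `s0`).
#' @param seed Optional seed.
#' @param mask Optional logical array; voxels outside are zero-filled.
#' @param rician If `TRUE`, apply Rician (magnitude) noise instead of plain
#'   additive Gaussian.
#' @return 4D array (x, y, z, echo) with attribute `echo_times`.
#' @export
synthesize_echo_series <- function(s0, relax, echo_times, noise_sd = 0,
                                   seed = NULL, mask = NULL, rician = FALSE) {
  if (is.null(dim(s0)) && length(s0) == 1) {
    stopifnot(!is.null(dim(relax)) || length(relax) == 1)
  }
  if (length(relax) == 1 && length(s0) > 1) relax <- array(relax, dim(s0))
  if (length(s0) == 1 && length(relax) > 1) s0 <- array(s0, dim(relax))
  if (length(s0) == 1) { s0 <- array(s0, c(1, 1, 1)); relax <- array(relax, c(1, 1, 1)) }
  stopifnot(all(dim(s0) == dim(relax)))
  if (any(!is.finite(echo_times)) || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("echo times must be strictly increasing and positive")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(s0))
  if (any(relax[mask] <= 0, na.rm = TRUE)) {
    stop("nonpositive relaxation time inside the mask")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  ne <- length(echo_times)
  out <- array(0, c(dim(s0), ne))
  r <- ifelse(mask & relax > 0, 1 / relax, NA_real_)
  for (e in seq_len(ne)) {
    sig <- ifelse(mask, s0 * exp(-echo_times[e] * r), 0)
    if (noise_sd > 0) {
      if (rician) {
        sig <- sqrt((sig + stats::rnorm(length(sig), 0, noise_sd))^2 +
                      stats::rnorm(length(sig), 0, noise_sd)^2)
      } else {
        sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
      }
    }
    out[, , , e] <- sig
  }
  attr(out, "echo_times") <- echo_times
  out
}

#' Default diffusion acquisition protocol
#'
#' 60 unique gradient directions (deterministic Fibonacci-sphere layout) at
#' b = 2000 s/mm^2 plus 4 non-diffusion-weighted volumes.
#' @param n_dir Number of diffusion-weighted directions.
#' @param n_b0 Number of b = 0 volumes.
#' @param b b-value (s/mm^2) of the weighted volumes.
#' @return List with `bvals` (length `n_b0 + n_dir`) and `bvecs`
#'   (`(n_b0 + n_dir) x 3`, zero rows for b = 0).
#' @export
dwi_protocol <- function(n_dir = 60, n_b0 = 4, b = 2000) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dir
  rho <- sqrt(pmax(1 - z^2, 0))
  dirs <- cbind(rho * cos(phi), rho * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  list(bvals = c(rep(0, n_b0), rep(b, n_dir)),
       bvecs = rbind(matrix(0, n_b0, 3), dirs))
}

#' Synthesize diffusion-weighted signals from a tensor field
#'
#' Single-tensor model: `S = S0 * exp(-b * g' D g) + noise` per voxel and
#' gradient direction.
#'
#' @param tensors Either a length-6 vector (one tensor for all voxels) or an
#'   `n x 6` matrix of unique components ordered
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in mm^2/s.
#' @param bvals b-values per volume (s/mm^2).
#' @param bvecs Volume x 3 matrix of gradient directions; must be unit norm
#'   where `b > 0`.
#' @param s0 Non-diffusion-weighted signal (scalar or length-n).
#' @param noise_sd,seed,rician As in [synthesize_echo_series()].
#' @return `n x nvolume` signal matrix with attributes `bvals`, `bvecs`.
#' @export
synthesize_dwi <- function(tensors, bvals, bvecs, s0 = 100, noise_sd = 0,
                           seed = NULL, rician = FALSE) {
  if (is.null(dim(tensors))) tensors <- matrix(tensors, 1)
  stopifnot(ncol(tensors) == 6, nrow(bvecs) == length(bvals))
  ev <- eigenvalues_sym3(tensors)
  if (any(ev[, 3] < -1e-12 * pmax(ev[, 1], 1e-300))) {
    stop("tensors must be symmetric positive semidefinite")
  }
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[bvals > 0] - 1) > 1e-6)) {
    stop("gradient directions must be unit norm where b > 0")
  }
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  # design of quadratic form per volume: g' D g
  G <- cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
             2 * bvecs[, 1] * bvecs[, 2],
             2 * bvecs[, 1] * bvecs[, 3],
             2 * bvecs[, 2] * bvecs[, 3])
  q <- tensors %*% t(G)               # n x nvol
  sig <- s0 * exp(-sweep(q, 2, bvals, `*`))
  if (noise_sd > 0) {
    if (rician) {
      sig <- sqrt((sig + stats::rnorm(length(sig), 0, noise_sd))^2 +
                    stats::rnorm(length(sig), 0, noise_sd)^2)
    } else {
      sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    }
  }
  attr(sig, "bvals") <- bvals
  attr(sig, "bvecs") <- bvecs
  sig
}

# default C-shaped arc placement for one side: chord along y, the two arcs
# bulging laterally away from the midline, with a slight out-of-plane tilt so
# the curve is genuinely 3D
default_side_geometry <- function(grid, axis_len, side) {
  ext <- grid_extent(grid)
  theta <- 1.75                        # arc opening angle (rad)
  R <- axis_len / theta
  tilt <- 0.18
  sgn <- if (side == "ipsi") -1 else 1
  center <- c(ext[1] * (0.5 - sgn * 0.03), ext[2] * 0.5, ext[3] * 0.45)
  arc_centerline(center, R, u = c(0, 1, 0),
                 v = c(sgn * cos(tilt), 0, sin(tilt)),
                 theta0 = pi / 2 - theta / 2, length_mm = axis_len)
}

default_radius_profile <- function(axis_len) {
  force(axis_len)
  function(s) 1.5 - 0.4 * (abs(s - axis_len / 2) / (axis_len / 2))^2
}

#' Generate a complete synthetic cohort
#'
#' Draws group labels (deterministic rounding of the prevalences, seeded
#' assignment), builds per-animal hippocampus masks for both sides with
#' day-dependent atrophy for TBI animals, and generates all quantitative
#' parameter maps (T2/T2* on D2/D7/D21; diffusion scalars on D7/D21 only).
#'
#' @param config A [cohort_config()].
#' @param verbose Print progress.
#' @return A `hippo_cohort` list with `config`, `grid`, `labels` (tibble:
#'   animal_id, group, epilepsy, cognition) and `animals`; each animal holds
#'   per-side compact mask/projection data, per-day masks, maps and volumes.
#' @export
generate_cohort <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_sham + config$n_tbi
  if (n == 0) stop("empty cohort requested")
  withr::local_seed(config$seed)
  ids <- sprintf("A%03d", seq_len(n))
  group <- rep(c("sham", "TBI"), c(config$n_sham, config$n_tbi))
  epi <- cog <- rep(NA, n)
  if (config$n_tbi > 0) {
    n_epi <- round(config$epilepsy_prev * config$n_tbi)
    n_ci <- round(config$ci_prev * config$n_tbi)
    tbi_idx <- which(group == "TBI")
    epi[tbi_idx] <- FALSE
    cog[tbi_idx] <- FALSE
    epi[sample(tbi_idx, n_epi)] <- TRUE
    cog[sample(tbi_idx, n_ci)] <- TRUE
  }
  labels <- tibble::tibble(animal_id = ids, group = group,
                           epilepsy = epi, cognition = cog)
  rad <- default_radius_profile(config$axis_len)
  days <- c("D2", "D7", "D21")
  voxvol <- voxel_volume(config$grid)
  base_mk <- NULL
  if (config$geometry_jitter == 0) {
    # shared geometry: rasterize and project each side once for the cohort
    base_mk <- lapply(stats::setNames(c("ipsi", "contra"),
                                      c("ipsi", "contra")), function(side) {
      generate_mask(config$grid,
                    default_side_geometry(config$grid, config$axis_len, side),
                    rad)
    })
  }
  animals <- vector("list", n)
  names(animals) <- ids
  for (a in seq_len(n)) {
    animal <- list(id = ids[a], group = group[a],
                   epilepsy = if (group[a] == "TBI") epi[a] else NA,
                   cognition = if (group[a] == "TBI") cog[a] else NA)
    animal_off <- stats::rnorm(length(config$animal_sd), 0, config$animal_sd)
    names(animal_off) <- names(config$animal_sd)
    sides <- list()
    for (side in c("ipsi", "contra")) {
      if (is.null(base_mk)) {
        spec <- default_side_geometry(config$grid, config$axis_len, side)
        spec$center <- spec$center +
          stats::rnorm(3, 0, config$geometry_jitter * c(1, 1, 0.5))
        mk <- generate_mask(config$grid, spec, rad)
      } else {
        mk <- base_mk[[side]]
      }
      scale_base <- config$atrophy[[side]]
      masks <- list(); maps <- list(); vols <- numeric(0)
      for (d in days) {
        sc <- if (group[a] == "TBI") scale_base[[d]] else 1
        # per-animal mask-scale jitter; suppressed in shared-geometry mode
        if (config$geometry_jitter > 0) {
          sc <- sc * exp(stats::rnorm(1, 0, 0.015))
        }
        sc <- min(sc, 1)
        keep <- mk$proj$dist <= sc * rad(mk$proj$s)
        masks[[d]] <- which(keep)
        vols[[d]] <- sum(keep) * voxvol
        sub <- structure(list(mask = NULL, indices = mk$indices[keep],
                              proj = list(s = mk$proj$s[keep],
                                          dist = mk$proj$dist[keep]),
                              centerline = mk$centerline, radius = mk$radius,
                              grid = config$grid), class = "hippo_mask")
        maps[[d]] <- generate_parameter_maps(
          sub, animal, d, side = side, effects = config$effects,
          baselines = config$baselines, noise_sd = config$noise_sd,
          animal_offset = animal_off, values_only = TRUE)
      }
      sides[[side]] <- list(side = side, centerline = mk$centerline,
                            radius = mk$radius, indices = mk$indices,
                            proj = mk$proj, masks = masks, maps = maps,
                            volumes = vols)
    }
    animal$sides <- sides
    animals[[a]] <- animal
    if (verbose && a %% 10 == 0) message("generated ", a, "/", n, " animals")
  }
  structure(list(config = config, grid = config$grid, labels = labels,
                 animals = animals),
            class = "hippo_cohort")
}

#' @export
print.hippo_cohort <- function(x, ...) {
  lab <- x$labels
  cat(sprintf("hippo_cohort: %d animals (%d sham, %d TBI; %d TBI+, %d CI+)\n",
              nrow(lab), sum(lab$group == "sham"), sum(lab$group == "TBI"),
              sum(lab$epilepsy, na.rm = TRUE), sum(lab$cognition, na.rm = TRUE)))
  invisible(x)
}

#' Cohort label table
#' @param cohort A `hippo_cohort`.
#' @return Tibble with columns animal_id, group, epilepsy, cognition.
#' @export
cohort_labels <- function(cohort) cohort$labels

#' Hippocampal volume table for a cohort
#'
#' @param cohort A `hippo_cohort`.
#' @return Tibble: animal_id, side, day, volume_mm3.
#' @export
cohort_volumes <- function(cohort) {
  rows <- lapply(cohort$animals, function(an) {
    do.call(rbind, lapply(an$sides, function(sd) {
      data.frame(animal_id = an$id, side = sd$side,
                 day = names(sd$volumes),
                 volume_mm3 = unname(sd$volumes))
    }))
  })
  tibble::as_tibble(do.call(rbind, c(rows, make.row.names = FALSE)))
}
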