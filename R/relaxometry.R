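#' T2/T2* relaxometry by monoexponential nonlinear least squares
#'
#' The decay model is `S(TE) = S0 * exp(-TE / T)` with `S0 > 0` and
#' `T in (0, t_max]`. For fixed `T` the optimal `S0` has a closed form, so the
#' fit is solved by variable projection: the profiled residual sum of squares
#' is minimized over the rate `1/T` by a log-spaced candidate scan seeded with
#' the log-linear estimate, followed by golden-section refinement. Everything
#' is vectorized across voxels, which keeps whole-volume fits fast.
#'
#' Flags: 0 = clean fit, 1 = `T` clipped at `t_max` (decay too slow to be
#' identified from the sampled window), 2 = undefined (no positive signal).
#' @name relaxometry
NULL

# profiled RSS at rates r (one per row of S); S0 constrained nonnegative
.monoexp_rss <- function(r, S, te, ss) {
  e <- exp(-outer(r, te))
  cc <- pmax(rowSums(S * e), 0)
  ss - cc^2 / rowSums(e * e)
}

# core vectorized fitter: S is nvox x necho, te strictly increasing (ms)
monoexp_fit_engine <- function(S, te, t_max = 2 * max(te), n_grid = 40,
                               tol = 1e-7) {
  nvox <- nrow(S); ne <- length(te)
  stopifnot(ne >= 2, ncol(S) == ne)
  ss <- rowSums(S^2)
  ok <- apply(S > 0, 1, any)
  t_min <- min(te) / 50
  r_lo <- 1 / t_max; r_hi <- 1 / t_min

  # log-linear seed over positive signals (slope of log S vs TE)
  r_ll <- rep(NA_real_, nvox)
  pos <- S > 0
  npos <- rowSums(pos)
  two <- which(ok & npos >= 2)
  if (length(two)) {
    W <- pos[two, , drop = FALSE] * 1
    L <- log(ifelse(pos[two, , drop = FALSE], S[two, , drop = FALSE], 1))
    sw <- rowSums(W)
    mx <- (W %*% te) / sw
    my <- rowSums(W * L) / sw
    sxx <- (W %*% te^2) / sw - mx^2
    sxy <- rowSums(W * sweep(L, 2, te, `*`)) / sw - mx * my
    slope <- ifelse(sxx > 0, sxy / sxx, 0)
    r_ll[two] <- pmin(pmax(-slope, r_lo), r_hi)
  }
  r_ll[ok & npos < 2] <- r_lo

  # candidate scan on a shared log-spaced rate grid plus the per-voxel seed
  r_grid <- exp(seq(log(r_lo), log(r_hi), length.out = n_grid))
  best_r <- rep(r_lo, nvox); best_f <- rep(Inf, nvox)
  idx_ok <- which(ok)
  if (length(idx_ok)) {
    Sok <- S[idx_ok, , drop = FALSE]; ssok <- ss[idx_ok]
    E <- exp(-outer(r_grid, te))                 # n_grid x ne
    CC <- pmax(Sok %*% t(E), 0)                  # nvox_ok x n_grid
    den <- rowSums(E * E)
    RSS <- ssok - sweep(CC^2, 2, den, `/`)
    bi <- max.col(-RSS, ties.method = "first")
    best_r[idx_ok] <- r_grid[bi]
    best_f[idx_ok] <- RSS[cbind(seq_along(idx_ok), bi)]
    f_ll <- .monoexp_rss(r_ll[idx_ok], Sok, te, ssok)
    upd <- f_ll < best_f[idx_ok]
    best_r[idx_ok][upd] <- r_ll[idx_ok][upd]
    best_f[idx_ok][upd] <- f_ll[upd]

    # golden-section refinement in log-rate within one grid step either side
    stepf <- log(r_grid[2] / r_grid[1])
    lo <- pmax(log(best_r[idx_ok]) - stepf, log(r_lo))
    hi <- pmin(log(best_r[idx_ok]) + stepf, log(r_hi))
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- .monoexp_rss(exp(x1), Sok, te, ssok)
    f2 <- .monoexp_rss(exp(x2), Sok, te, ssok)
    for (it in seq_len(35)) {
      left <- f1 <= f2
      hi[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
      x1[left] <- hi[left] - gr * (hi[left] - lo[left])
      if (any(left)) {
        f1[left] <- .monoexp_rss(exp(x1[left]), Sok[left, , drop = FALSE],
                                 te, ssok[left])
      }
      rt <- !left
      lo[rt] <- x1[rt]; x1[rt] <- x2[rt]; f1[rt] <- f2[rt]
      x2[rt] <- lo[rt] + gr * (hi[rt] - lo[rt])
      if (any(rt)) {
        f2[rt] <- .monoexp_rss(exp(x2[rt]), Sok[rt, , drop = FALSE],
                               te, ssok[rt])
      }
      if (max(hi - lo) < 1e-6) break
    }
    xm <- (lo + hi) / 2
    fm <- .monoexp_rss(exp(xm), Sok, te, ssok)
    upd <- fm < best_f[idx_ok]
    best_r[idx_ok][upd] <- exp(xm[upd])
    best_f[idx_ok][upd] <- fm[upd]
  }

  t_hat <- 1 / best_r
  e <- exp(-outer(best_r, te))
  s0_hat <- pmax(rowSums(S * e), 0) / rowSums(e * e)
  flag <- integer(nvox)
  clip <- ok & t_hat >= t_max * (1 - 1e-6)
  t_hat[clip] <- t_max
  flag[clip] <- 1L
  t_hat[!ok] <- NA_real_; s0_hat[!ok] <- NA_real_; best_f[!ok] <- NA_real_
  flag[!ok] <- 2L
  list(s0 = s0_hat, t = t_hat, rss = best_f, flag = flag)
}

#' Fit a monoexponential decay to one voxel's echo signals
#'
#' @param signals Numeric vector of echo intensities.
#' @param times Echo times (ms), strictly increasing, positive.
#' @param t_max Upper bound for the relaxation time (ms); defaults to twice
#'   the last echo time, beyond which the decay is unidentifiable from the
#'   sampled window.
#' @return List with `s0`, `t` (ms), `rss`, `flag` (see [relaxometry]) and
#'   `flagged` (logical).
#' @examples
#' te <- c(14.6, 29.2, 43.8, 58.4, 73.0, 87.6)
#' fit <- fit_monoexponential(100 * exp(-te / 50), te)
#' round(c(fit$s0, fit$t), 3)
#' @export
fit_monoexponential <- function(signals, times, t_max = 2 * max(times)) {
  if (length(times) < 2) stop("at least two echoes are required")
  if (any(!is.finite(times)) || any(times <= 0) || any(diff(times) <= 0)) {
    stop("echo times must be strictly increasing and positive")
  }
  stopifnot(length(signals) == length(times))
  res <- monoexp_fit_engine(matrix(signals, 1), times, t_max = t_max)
  list(s0 = res$s0, t = res$t, rss = res$rss, flag = res$flag,
       flagged = res$flag != 0L)
}

#' Fit a relaxation-time map over a masked volume
#'
#' Applies the monoexponential fit of [fit_monoexponential()] to every
#' in-mask voxel of a 4D multi-echo series; out-of-mask voxels carry `NA`.
#'
#' @param series 4D array (x, y, z, echo); may carry an `echo_times`
#'   attribute.
#' @param mask Logical 3D array matching the spatial dimensions.
#' @param echo_times Echo times (ms); defaults to the series attribute.
#' @param grid Optional [voxel_grid()] carried through to the output.
#' @param t_max As in [fit_monoexponential()].
#' @param parameter Name stored on the output map (`"T2"` or `"T2star"`).
#' @return 3D `parameter_map` array of relaxation times (ms) with attributes
#'   `s0` (matching 3D array) and `qc` (named counts of flagged voxels).
#' @export
fit_relaxation_map <- function(series, mask, echo_times = attr(series, "echo_times"),
                               grid = NULL, t_max = NULL, parameter = "T2") {
  d <- dim(series)
  if (length(d) != 4) stop("series must be a 4D array (x, y, z, echo)")
  if (is.null(echo_times)) stop("echo times are required")
  if (length(echo_times) != d[4]) stop("echo count mismatch with series")
  if (!all(dim(mask) == d[1:3])) stop("mask and series grids do not match")
  if (!is.null(grid) && !all(grid$shape == d[1:3])) {
    stop("voxel grid does not match the series")
  }
  if (is.null(t_max)) t_max <- 2 * max(echo_times)
  idx <- which(mask)
  tmap <- array(NA_real_, d[1:3]); s0map <- array(NA_real_, d[1:3])
  qc <- c(clipped = 0L, undefined = 0L)
  if (length(idx)) {
    Sm <- matrix(series, prod(d[1:3]), d[4])[idx, , drop = FALSE]
    res <- monoexp_fit_engine(Sm, echo_times, t_max = t_max)
    tmap[idx] <- res$t
    s0map[idx] <- res$s0
    qc <- c(clipped = sum(res$flag == 1L), undefined = sum(res$flag == 2L))
  }
  structure(tmap, grid = grid, parameter = parameter, s0 = s0map, qc = qc,
            class = c("parameter_map", "array"))
}
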