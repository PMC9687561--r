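#' Diffusion tensor estimation and scalar maps
#'
#' Single-tensor fits by ordinary least squares on log-signals, and the
#' derived scalar measures: sorted eigenvalues, fractional anisotropy (FA),
#' mean diffusivity (MD), radial diffusivity (RD) and the Westin shape
#' measures. The Westin measures use the trace-normalized convention
#' `c_l = (l1 - l2) / (l1 + l2 + l3)`, `c_p = 2 (l2 - l3) / (l1 + l2 + l3)`,
#' `c_s = 3 l3 / (l1 + l2 + l3)`, which sum to one for every defined voxel.
#' @name diffusion_metrics
NULL

# closed-form eigenvalues of symmetric 3x3 tensors, vectorized.
# x: n x 6 matrix (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz). Returns n x 3, descending.
eigenvalues_sym3 <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  a11 <- x[, 1]; a22 <- x[, 2]; a33 <- x[, 3]
  a12 <- x[, 4]; a13 <- x[, 5]; a23 <- x[, 6]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  n <- length(q)
  out <- matrix(q, n, 3)
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    # enforce descending order against float roundoff in near-degenerate cases
    t1 <- pmax(e1, e2); t2 <- pmin(e1, e2)
    l1 <- pmax(t1, e3); l3 <- pmin(t2, e3)
    l2 <- pmin(pmax(e1 + e2 + e3 - l1 - l3, l3), l1)
    out[nz, ] <- cbind(l1, l2, l3)
  }
  out
}

#' Scalar measures from sorted tensor eigenvalues
#'
#' @param eigenvalues Length-3 vector or `n x 3` matrix of eigenvalues in
#'   mm^2/s, sorted descending, nonnegative.
#' @return Named list (or list of vectors) with `FA`, `MD`, `RD`, `lambda1`,
#'   `lambda2`, `lambda3`, `cl`, `cp`, `cs`. All-zero triples yield `NA`
#'   scalars and are flagged via the `flagged` element.
#' @examples
#' tensor_scalars(c(2, 0.5, 0.5) * 1e-3)[c("FA", "cl", "cs")]
#' @export
tensor_scalars <- function(eigenvalues) {
  ev <- if (is.null(dim(eigenvalues))) matrix(eigenvalues, 1) else eigenvalues
  stopifnot(ncol(ev) == 3)
  # tolerate ulp-level inversions from degenerate (equal-eigenvalue) tensors
  tol <- 1e-8 * pmax(abs(ev[, 1]), .Machine$double.xmin)
  if (any(ev[, 1] < ev[, 2] - tol | ev[, 2] < ev[, 3] - tol, na.rm = TRUE)) {
    stop("eigenvalues must be sorted descending")
  }
  if (any(ev < -1e-12, na.rm = TRUE)) stop("eigenvalues must be nonnegative")
  l1 <- ev[, 1]
  l3 <- pmin(ev[, 3], ev[, 2], l1)
  l2 <- pmin(pmax(ev[, 2], l3), l1)
  tr <- l1 + l2 + l3
  zero <- !is.na(tr) & tr <= 0
  tr_safe <- ifelse(tr > 0, tr, NA_real_)
  md <- tr / 3
  rd <- (l2 + l3) / 2
  nrm <- sqrt(l1^2 + l2^2 + l3^2)
  dev <- sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2)
  fa <- ifelse(nrm > 0, sqrt(3 / 2) * dev / nrm, NA_real_)
  res <- list(FA = fa, MD = ifelse(zero, NA_real_, md),
              RD = ifelse(zero, NA_real_, rd),
              lambda1 = l1, lambda2 = l2, lambda3 = l3,
              cl = (l1 - l2) / tr_safe,
              cp = 2 * (l2 - l3) / tr_safe,
              cs = 3 * l3 / tr_safe,
              flagged = zero)
  if (is.null(dim(eigenvalues))) lapply(res, function(v) v[1]) else res
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Ordinary least squares of `log S` on the six tensor design columns plus
#' `log S0`, per voxel. Voxels with nonpositive signals drop those volumes;
#' a voxel is rejected (NA, flagged) when fewer than 7 usable volumes remain.
#' Negative eigenvalues are clamped to zero and flagged.
#'
#' @param signals Either a 4D array (x, y, z, volume) or an `n x nvolume`
#'   matrix of voxel signals.
#' @param bvals b-values (s/mm^2) per volume; at least one must be 0.
#' @param bvecs Volume x 3 gradient directions (unit norm where b > 0).
#' @param mask Logical 3D array (for 4D input) or length-n logical.
#' @return A `tensor_field` list: `tensors` (n x 6), `evals` (n x 3 sorted
#'   descending, clamped), `s0`, `flags` (`rejected`, `clamped` logicals),
#'   `index` (voxel linear indices for array input), `dim` (spatial dims, if
#'   any).
#' @export
fit_tensor_loglinear <- function(signals, bvals, bvecs, mask = NULL) {
  arr <- length(dim(signals)) == 4
  if (arr) {
    d <- dim(signals)
    if (is.null(mask)) mask <- array(TRUE, d[1:3])
    if (!all(dim(mask) == d[1:3])) stop("mask and series grids do not match")
    idx <- which(mask)
    S <- matrix(signals, prod(d[1:3]), d[4])[idx, , drop = FALSE]
    spat <- d[1:3]
  } else {
    S <- if (is.null(dim(signals))) matrix(signals, 1) else signals
    if (!is.null(mask)) S <- S[mask, , drop = FALSE]
    idx <- seq_len(nrow(S))
    spat <- NULL
  }
  nvol <- ncol(S)
  stopifnot(length(bvals) == nvol, nrow(bvecs) == nvol)
  if (!any(bvals == 0)) stop("at least one b = 0 volume is required")
  if (nvol < 7) stop("at least 7 volumes are required")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm[bvals > 0] - 1) > 1e-6)) {
    stop("gradient directions must be unit norm where b > 0")
  }
  Xg <- cbind(bvecs[, 1]^2, bvecs[, 2]^2, bvecs[, 3]^2,
              2 * bvecs[, 1] * bvecs[, 2],
              2 * bvecs[, 1] * bvecs[, 3],
              2 * bvecs[, 2] * bvecs[, 3])
  X <- cbind(1, -bvals * Xg)
  if (qr(X[bvals > 0, -1, drop = FALSE])$rank < 6) {
    stop("insufficient directions: fewer than 6 independent gradient directions")
  }
  n <- nrow(S)
  usable <- S > 0
  full <- rowSums(usable) == nvol
  B <- matrix(NA_real_, n, 7)
  if (any(full)) {
    # one shared solve for the (typical) voxels with all volumes usable
    fit <- qr.coef(qr(X), t(log(S[full, , drop = FALSE])))
    B[full, ] <- t(fit)
  }
  part <- which(!full & rowSums(usable) >= 7)
  for (v in part) {
    u <- usable[v, ]
    Xu <- X[u, , drop = FALSE]
    if (qr(Xu)$rank < 7) next
    B[v, ] <- qr.solve(Xu, log(S[v, u]))
  }
  rejected <- is.na(B[, 1])
  tensors <- B[, 2:7, drop = FALSE]
  ev <- matrix(NA_real_, n, 3)
  ok <- which(!rejected)
  if (length(ok)) ev[ok, ] <- eigenvalues_sym3(tensors[ok, , drop = FALSE])
  clamped <- !rejected & (ev[, 3] < 0)
  clamped[is.na(clamped)] <- FALSE
  ev[ev < 0] <- 0
  structure(list(tensors = tensors, evals = ev, s0 = exp(B[, 1]),
                 flags = list(rejected = rejected, clamped = clamped),
                 index = idx, dim = spat),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %d voxels (%d rejected, %d clamped)\n",
              nrow(x$tensors), sum(x$flags$rejected), sum(x$flags$clamped)))
  invisible(x)
}

#' Scalar maps from a fitted tensor field
#'
#' @param field A `tensor_field` from [fit_tensor_loglinear()].
#' @param grid Optional [voxel_grid()] attached to the output maps.
#' @return Named list of 3D `parameter_map` arrays (when the field was fitted
#'   from a 4D series) or a list of per-voxel vectors otherwise.
#' @export
tensor_scalar_maps <- function(field, grid = NULL) {
  stopifnot(inherits(field, "tensor_field"))
  sc <- tensor_scalars_nocheck(field$evals)
  nm <- c("FA", "MD", "RD", "lambda1", "lambda2", "lambda3", "cl", "cp", "cs")
  if (is.null(field$dim)) return(sc[nm])
  lapply(stats::setNames(nm, nm), function(p) {
    a <- array(NA_real_, field$dim)
    a[field$index] <- sc[[p]]
    structure(a, grid = grid, parameter = p,
              class = c("parameter_map", "array"))
  })
}

# as tensor_scalars() but tolerant of NA rows (rejected voxels)
tensor_scalars_nocheck <- function(ev) {
  keep <- !is.na(ev[, 1])
  out <- list(FA = rep(NA_real_, nrow(ev)))
  nm <- c("FA", "MD", "RD", "lambda1", "lambda2", "lambda3", "cl", "cp", "cs")
  for (p in nm) out[[p]] <- rep(NA_real_, nrow(ev))
  if (any(keep)) {
    sc <- tensor_scalars(ev[keep, , drop = FALSE])
    for (p in nm) out[[p]][keep] <- sc[[p]]
  }
  out
}
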