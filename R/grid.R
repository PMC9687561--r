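#' Voxel grid geometry
#'
#' A `voxel_grid` describes an anisotropic 3D voxel lattice by its integer
#' shape and physical voxel dimensions in millimetres. Voxel centres sit at
#' `(i - 0.5) * dx` along each axis, so the grid spans `shape * vox_mm` mm.
#'
#' @param shape Integer vector of length 3, number of voxels per axis.
#' @param vox_mm Numeric vector of length 3, voxel edge lengths in mm.
#'   Defaults to 0.20 mm in-plane and 0.50 mm slice thickness, the
#'   acquisition class this pipeline targets (0.15-0.20 mm in-plane).
#' @return An object of class `voxel_grid` with fields `shape` and `vox_mm`.
#' @examples
#' g <- voxel_grid(c(64, 64, 24))
#' grid_extent(g)
#' @export
voxel_grid <- function(shape, vox_mm = c(0.20, 0.20, 0.50)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, length(vox_mm) == 3)
  if (any(shape < 1L)) stop("grid shape components must be >= 1")
  if (any(!is.finite(vox_mm)) || any(vox_mm <= 0)) {
    stop("voxel dimensions must be strictly positive")
  }
  structure(list(shape = shape, vox_mm = as.numeric(vox_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels at %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$vox_mm[1], x$vox_mm[2], x$vox_mm[3]))
  invisible(x)
}

#' Physical extent of a grid in mm
#' @param grid A [voxel_grid()].
#' @return Numeric length-3 vector of physical extents (mm).
#' @export
grid_extent <- function(grid) grid$shape * grid$vox_mm

#' Volume of one voxel in mm^3
#' @param grid A [voxel_grid()].
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$vox_mm)

# i/j/k array indices (1-based) -> physical mm coordinates of voxel centres
ijk_to_mm <- function(ijk, grid) {
  sweep(ijk - 0.5, 2, grid$vox_mm, `*`)
}

# linear indices into the grid array -> n x 3 matrix of voxel-centre mm coords
index_to_mm <- function(idx, grid) {
  ijk_to_mm(index_to_ijk(idx, grid), grid)
}

index_to_ijk <- function(idx, grid) {
  idx0 <- idx - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  i <- idx0 %% nx
  j <- (idx0 %/% nx) %% ny
  k <- idx0 %/% (nx * ny)
  cbind(i, j, k) + 1L
}

ijk_to_index <- function(ijk, grid) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  as.integer((ijk[, 3] - 1L) * nx * ny + (ijk[, 2] - 1L) * nx + ijk[, 1])
}

# logical 3D array from linear indices
indices_to_array <- function(idx, grid) {
  a <- array(FALSE, dim = grid$shape)
  a[idx] <- TRUE
  a
}

check_same_grid <- function(a, b) {
  if (!identical(a$shape, b$shape) || !isTRUE(all.equal(a$vox_mm, b$vox_mm))) {
    stop("voxel grids do not match")
  }
  invisible(TRUE)
}

# grid attached to an array-valued object, if any
grid_of <- function(x) {
  g <- attr(x, "grid")
  if (is.null(g)) stop("object carries no voxel_grid attribute")
  g
}
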