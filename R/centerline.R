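#' Analytic centerline curves
#'
#' Centerline specifications describe the true midline of a synthetic
#' hippocampus-shaped tube. Two families are provided: a straight segment and
#' a circular arc (the C-shape of the rodent hippocampus seen from the side).
#' Both are sampled densely into a polyline carrying exact arc length, which
#' downstream code uses as the projection oracle.
#'
#' @param start Numeric length-3, start point (mm).
#' @param direction Numeric length-3, direction of travel (normalized
#'   internally).
#' @param length_mm Total arc length of the curve (mm).
#' @return A `centerline_spec` list.
#' @export
straight_centerline <- function(start, direction, length_mm) {
  d <- direction / sqrt(sum(direction^2))
  structure(list(type = "straight", start = as.numeric(start), direction = d,
                 length_mm = as.numeric(length_mm)),
            class = "centerline_spec")
}

#' @rdname straight_centerline
#' @param center Arc centre (mm).
#' @param radius_mm Arc radius (mm).
#' @param u,v Orthonormal in-plane axes of the arc plane; `v` is
#'   orthogonalized against `u` internally.
#' @param theta0 Starting angle (radians) within the `u`/`v` plane.
#' @export
arc_centerline <- function(center, radius_mm, u, v, theta0 = 0, length_mm) {
  u <- u / sqrt(sum(u^2))
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("arc plane axes are collinear")
  v <- v / nv
  structure(list(type = "arc", center = as.numeric(center),
                 radius_mm = as.numeric(radius_mm), u = u, v = v,
                 theta0 = as.numeric(theta0), length_mm = as.numeric(length_mm)),
            class = "centerline_spec")
}

#' Densely sample a centerline specification
#'
#' @param spec A `centerline_spec`.
#' @param step Arc-length sampling step (mm).
#' @return List with `points` (n x 3 mm) and `s` (arc length from the
#'   temporal end, mm).
#' @export
sample_centerline <- function(spec, step = 0.02) {
  stopifnot(inherits(spec, "centerline_spec"))
  s <- seq(0, spec$length_mm, by = step)
  if (s[length(s)] < spec$length_mm) s <- c(s, spec$length_mm)
  pts <- switch(spec$type,
    straight = {
      outer(s, spec$direction) + rep(spec$start, each = length(s))
    },
    arc = {
      th <- spec$theta0 + s / spec$radius_mm
      ca <- cos(th); sa <- sin(th)
      p <- outer(ca, spec$u) + outer(sa, spec$v)
      spec$radius_mm * p + rep(spec$center, each = length(s))
    },
    stop("unknown centerline type")
  )
  list(points = pts, s = s)
}

# Nearest-point projection of an n x 3 point set onto a sampled polyline.
# Returns, per point, the arc length s of the nearest polyline sample and the
# Euclidean distance to it. Ties resolve to the smaller s (which.min / max.col
# first-hit semantics on an ascending-s polyline). Chunked to bound memory.
project_points_to_polyline <- function(points, poly, chunk = 2048L) {
  pts <- poly$points
  m <- nrow(pts)
  n <- nrow(points)
  s_out <- numeric(n)
  d_out <- numeric(n)
  pp <- rowSums(pts^2)
  i0 <- 1L
  while (i0 <= n) {
    i1 <- min(i0 + chunk - 1L, n)
    q <- points[i0:i1, , drop = FALSE]
    # squared distances via expansion; clamp tiny negatives from roundoff
    d2 <- outer(rowSums(q^2), pp, `+`) - 2 * q %*% t(pts)
    best <- max.col(-d2, ties.method = "first")
    rows <- seq_len(i1 - i0 + 1L)
    s_out[i0:i1] <- poly$s[best]
    d_out[i0:i1] <- sqrt(pmax(d2[cbind(rows, best)], 0))
    i0 <- i1 + 1L
  }
  list(s = s_out, dist = d_out)
}
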