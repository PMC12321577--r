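# Geometric primitives shared by the simulator and the morphometry
# operators. Point sets are n x 2 matrices in (y, x) micrometres.

#' Sample from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. kappa = 0 degenerates to the
#' uniform distribution on the circle; large kappa concentrates at `mu`.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, >= 0.
#' @return angles in `(-pi, pi]`, radians.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa > 5e5) return(rep(atan2(sin(mu), cos(mu)), n))  # numerically a point mass
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- atan2(sin(theta), cos(theta))
      i <- i + 1L
    }
  }
  out
}

#' Fold an angle onto [0, 90] degrees
#'
#' Orientation relative to an (unsigned, undirected) axis: angles are taken
#' modulo 180 and reflected so 0 means parallel and 90 perpendicular.
#' @param deg angle(s) in degrees.
#' @return angle(s) in `[0, 90]`.
#' @export
fold_angle_deg <- function(deg) {
  a <- abs(deg) %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Convex hull of a point set
#' @param pts n x 2 matrix (y, x).
#' @return hull vertices (counter-clockwise in (x, y) sense), m x 2 (y, x).
#' @export
convex_hull <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # chull takes (x, y)
  pts[h, , drop = FALSE]
}

# Signed polygon area (shoelace) for vertices in (y, x)
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 2]; y <- v[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Maximum Feret diameter and its axis
#'
#' Exact maximum caliper distance of a point set: the farthest pair of
#' convex-hull vertices. Returns the length and the unit axis direction.
#'
#' @param pts n x 2 matrix (y, x), micrometres.
#' @return list `length_um`, `axis` (unit (y, x) vector).
#' @export
max_feret <- function(pts) {
  h <- convex_hull(pts)
  if (nrow(h) < 2) stop("degenerate point set: fewer than 2 distinct points")
  d2 <- as.matrix(stats::dist(h))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  v <- h[ij[2], ] - h[ij[1], ]
  len <- sqrt(sum(v^2))
  list(length_um = len, axis = v / len)
}

#' Extent of a point set along a direction
#' @param pts n x 2 (y, x); @param axis unit (y, x) vector.
#' @return max minus min projection.
#' @export
extent_along <- function(pts, axis) {
  p <- pts %*% axis
  max(p) - min(p)
}

#' Angle between an axis and the midline, folded to [0, 90] degrees
#' @param axis unit (y, x) vector.
#' @param midline unit (y, x) vector.
#' @return degrees in `[0, 90]`.
#' @export
axis_angle_deg <- function(axis, midline) {
  ct <- abs(sum(axis * midline)) / (sqrt(sum(axis^2)) * sqrt(sum(midline^2)))
  acos(pmin(1, ct)) * 180 / pi
}

#' Principal axis of a point set
#'
#' First eigenvector of the covariance of the points; used for the
#' ground-truth orientation of sampled branch tips and as the optional
#' PCA-based orientation estimator.
#' @param pts n x 2 (y, x).
#' @return unit (y, x) vector.
#' @export
principal_axis <- function(pts) {
  stopifnot(nrow(pts) >= 2)
  cc <- sweep(pts, 2, colMeans(pts))
  e <- eigen(crossprod(cc) / nrow(pts), symmetric = TRUE)
  e$vectors[, 1]
}

#' Point-in-convex-polygon test
#' @param pts n x 2 (y, x); @param poly m x 2 hull vertices (y, x).
#' @return logical vector.
#' @export
points_in_polygon <- function(pts, poly) {
  if (nrow(poly) < 3) return(rep(FALSE, nrow(pts)))
  # winding via consistent side-of-edge test (poly convex, any orientation)
  m <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  # determine polygon orientation
  orient <- sum((poly[c(2:m, 1), 2] - poly[, 2]) * (poly[c(2:m, 1), 1] + poly[, 1]))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    cr <- (b[2] - a[2]) * (pts[, 1] - a[1]) - (b[1] - a[1]) * (pts[, 2] - a[2])
    inside <- inside & if (orient > 0) cr <= 1e-9 else cr >= -1e-9
  }
  inside
}

# Deterministic per-unit substream seed: mixing the run seed with a unit
# counter so adding a unit never perturbs the draws of the others.
substream_seed <- function(seed, counter) {
  s <- (as.double(seed) * 2654435761 + as.double(counter) * 97531) %% 2147483647
  as.integer(s)
}

with_substream <- function(seed, counter, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(substream_seed(seed, counter))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(expr)
}
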