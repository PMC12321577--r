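# Independent oracles and small constructors used across the test files.
# Each oracle re-derives a quantity by brute force, without reusing the
# package's algorithm under test.

# Wrap a logical matrix as an ArborMask (bypasses segmentation for tests of
# downstream geometry operators on hand-built shapes).
make_arbor <- function(mask, pixel_size_um = c(0.5, 0.5),
                       nucleus_yx_um = (dim(mask) - 1) / 2 * pixel_size_um) {
  structure(list(cell_id = 1L, mask = mask,
                 nucleus_yx_um = as.numeric(nucleus_yx_um),
                 pixel_size_um = as.numeric(pixel_size_um),
                 border_touching = FALSE),
            class = "ArborMask")
}

# Rotation-search Feret oracle: bounding-box extents on a 0.5 degree grid.
# Length = max extent over directions; width = extent perpendicular to the
# maximizing direction.
feret_rotation_oracle <- function(pts, step_deg = 0.5) {
  angs <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ext <- vapply(angs, function(a)
    extent_along(pts, c(cos(a), sin(a))), numeric(1))
  i <- which.max(ext)
  perp <- angs[i] + pi / 2
  list(length = ext[i],
       width = extent_along(pts, c(cos(perp), sin(perp))))
}

# Exhaustive optimal one-to-one matching oracle: maximizes pair count, then
# minimizes total distance, by recursion over all injective assignments.
# Only feasible for small instances (<= 8 spots per channel).
exhaustive_match_count <- function(A, B, max_dist) {
  n <- nrow(A); m <- nrow(B)
  if (n == 0 || m == 0) return(0L)
  D <- sqrt(outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2 +
            outer(A[, 3], B[, 3], `-`)^2)
  best_count <- 0L
  best_weight <- Inf
  used <- logical(m)
  rec <- function(i, count, weight) {
    if (count + (n - i + 1) < best_count) return()
    if (i > n) {
      if (count > best_count ||
          (count == best_count && weight < best_weight)) {
        best_count <<- count
        best_weight <<- weight
      }
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j] && D[i, j] <= max_dist) {
        used[j] <<- TRUE
        rec(i + 1L, count + 1L, weight + D[i, j])
        used[j] <<- FALSE
      }
    }
    rec(i + 1L, count, weight)   # leave pre i unmatched
  }
  rec(1L, 0L, 0)
  best_count
}

# Analytic circle / polyline crossing oracle for Sholl profiles: count
# parameter values t in (0, 1] where each straight polyline segment meets
# the circle of radius r about centre c.
circle_polyline_crossings <- function(polylines, centre, r) {
  total <- 0L
  for (poly in polylines) {
    if (nrow(poly) < 2) next
    for (k in seq_len(nrow(poly) - 1)) {
      p <- poly[k, ] - centre
      d <- poly[k + 1, ] - poly[k, ]
      A <- sum(d^2); B <- 2 * sum(p * d); C <- sum(p^2) - r^2
      disc <- B^2 - 4 * A * C
      if (A == 0 || disc <= 0) next
      ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
      total <- total + sum(ts > 0 & ts <= 1)
    }
  }
  total
}

# Star arbor with hand-chosen, well-separated branch directions (no random
# angular near-collisions), rasterized one pixel wide.
make_star_arbor <- function(angles_deg, length_um = 30, centre_um = c(40, 40),
                            pixel_size_um = c(0.2, 0.2), shape_px = c(401, 401)) {
  m <- matrix(FALSE, shape_px[1], shape_px[2])
  th <- angles_deg * pi / 180
  for (t in th) {
    tip <- centre_um + length_um * c(cos(t), sin(t))
    px <- septastro:::raster_segment(centre_um, tip, pixel_size_um,
                                     shape_px[1], shape_px[2])
    m[px] <- TRUE
  }
  make_arbor(m, pixel_size_um, centre_um)
}
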