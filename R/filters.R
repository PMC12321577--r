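# Separable Gaussian and Laplacian-of-Gaussian filtering on (z, y, x)
# arrays, with anisotropic voxel sizes. Internal to the detection operators.

gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k / sum(k)
}

# convolve a matrix along rows (dim 1) with reflective padding
conv_rows <- function(m, kernel) {
  lk <- length(kernel)
  if (lk == 1) return(m * kernel)
  r <- (lk - 1) / 2
  n <- nrow(m)
  padidx <- c(pmin(n, pmax(1, rev(seq_len(r)) + 1)),     # reflect top: r+1..2
              seq_len(n),
              pmin(n, pmax(1, n - seq_len(r))))          # reflect bottom: n-1..n-r
  mp <- m[padidx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_len(lk))
    out <- out + kernel[j] * mp[j:(j + n - 1), , drop = FALSE]
  out
}

# smooth a (z, y, x) array along one axis
smooth_axis <- function(arr, axis, sigma_px) {
  if (sigma_px <= 0) return(arr)
  d <- dim(arr)
  k <- gauss_kernel(sigma_px)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  m <- conv_rows(m, k)
  a <- array(m, dim = da)
  aperm(a, order(perm))
}

#' Anisotropic Gaussian smoothing of a z-stack channel
#' @param arr numeric array `(z, y, x)`.
#' @param sigma_um physical Gaussian sigma in micrometres; a scalar
#'   (isotropic) or a `(z, y, x)` vector.
#' @param voxel_size_um `(z, y, x)` micrometres per voxel.
#' @return smoothed array, same shape.
#' @export
gauss_smooth <- function(arr, sigma_um, voxel_size_um) {
  sigma_um <- rep_len(sigma_um, 3)
  for (ax in 1:3) {
    s_px <- sigma_um[ax] / voxel_size_um[ax]
    if (dim(arr)[ax] > 1) arr <- smooth_axis(arr, ax, s_px)
  }
  arr
}

# second difference along an axis, reflective edges, in physical units
second_diff_axis <- function(arr, axis, h_um) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 3) return(array(0, d))
  idx_p <- c(2, seq_len(n - 1))         # i-1 with reflection
  idx_n <- c(seq(2, n), n - 1)          # i+1 with reflection
  slice <- function(i) {
    ix <- list(quote(expr =), quote(expr =), quote(expr =))
    ix[[axis]] <- i
    do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
  }
  (slice(idx_p) + slice(idx_n) - 2 * arr) / h_um^2
}

#' Scale-normalised Laplacian-of-Gaussian blob response
#'
#' Smooths with an isotropic physical-scale Gaussian and applies the
#' (negative) Laplacian scaled by sigma^2, so bright Gaussian blobs of
#' matching scale give positive peaks whose height is intensity-comparable
#' across scales.
#'
#' @inheritParams gauss_smooth
#' @return response array `(z, y, x)`.
#' @export
log_response <- function(arr, sigma_um, voxel_size_um) {
  sigma_um <- rep_len(sigma_um, 3)
  sm <- gauss_smooth(arr, sigma_um, voxel_size_um)
  resp <- array(0, dim(arr))
  for (ax in 1:3)
    if (dim(arr)[ax] > 1)
      resp <- resp - sigma_um[ax]^2 *
        second_diff_axis(sm, ax, voxel_size_um[ax])
  resp
}

# strict local maxima over the 3x3x3 (or 3x3 when z is singleton)
# neighbourhood; returns integer matrix of (z, y, x) 1-based indices
local_maxima <- function(arr, threshold) {
  d <- dim(arr)
  ok <- arr > threshold
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dz == 0 & shifts$dy == 0 & shifts$dx == 0), ]
  pad <- array(-Inf, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  for (i in seq_len(nrow(shifts))) {
    s <- shifts[i, ]
    nb <- pad[(2 + s$dz):(d[1] + 1 + s$dz),
              (2 + s$dy):(d[2] + 1 + s$dy),
              (2 + s$dx):(d[3] + 1 + s$dx), drop = FALSE]
    ok <- ok & (arr >= nb)
    if (!any(ok)) break
  }
  # break plateau ties: require strictly greater than at least the
  # lexicographically earlier neighbours is overkill; dedupe later instead
  which(ok, arr.ind = TRUE)
}

# one-axis quadratic sub-voxel refinement around a maximum
quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (den >= 0) return(0)
  off <- 0.5 * (fm - fp) / den
  max(-0.5, min(0.5, off))
}

# robust automatic response floor: median + 5 * mad of the response image
# (response images are background-dominated, so median/mad track the noise)
auto_threshold <- function(resp) {
  v <- as.numeric(resp)
  stats::median(v) + 5 * stats::mad(v)
}
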