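# Per-astrocyte shape statistics: longest-branch distance, length-to-width
# ratio, midline-relative orientation with binning, territory size, and a
# Sholl profile. All operate on the 2-D maximum-projection segmentation.

#' Longest-branch distance
#'
#' Maximum Euclidean distance (micrometres) from the nucleus centroid to a
#' skeleton endpoint. A cyclic skeleton with no endpoints falls back to the
#' maximum over all skeleton pixels and flags the value.
#'
#' @param skel a `Skeleton` from [skeletonize_arbor()].
#' @param nucleus_yx_um nucleus centroid `(y, x)` micrometres; defaults to
#'   the one stored in the skeleton.
#' @return numeric distance with attribute `fallback` (TRUE when no
#'   endpoints existed).
#' @export
longest_branch <- function(skel, nucleus_yx_um = skel$nucleus_yx_um) {
  if (nrow(skel$pixels) == 0) stop("empty skeleton")
  if (nrow(skel$endpoints_um) > 0) {
    d <- sqrt(rowSums(sweep(skel$endpoints_um, 2, nucleus_yx_um)^2))
    out <- max(d)
    attr(out, "fallback") <- FALSE
  } else {
    pts <- (skel$pixels - 1) * rep(skel$pixel_size_um, each = nrow(skel$pixels))
    out <- max(sqrt(rowSums(sweep(pts, 2, nucleus_yx_um)^2)))
    attr(out, "fallback") <- TRUE
  }
  out
}

#' Length-to-width ratio of an arbor mask
#'
#' Length is the maximum Feret diameter of the mask (exact, from the
#' farthest convex-hull vertex pair); width is the mask extent along the
#' axis perpendicular to the max-Feret axis. The ratio is >= 1 up to pixel
#' discretisation.
#'
#' @param arbor an `ArborMask`.
#' @return list: `lw_ratio`, `length_um`, `width_um`, `axis` (unit (y, x)).
#' @export
length_width_ratio <- function(arbor) {
  pix <- which(arbor$mask, arr.ind = TRUE)
  if (nrow(pix) < 3) stop("degenerate mask: fewer than 3 pixels")
  pts <- (pix - 1) * rep(arbor$pixel_size_um, each = nrow(pix))
  f <- max_feret(pts)
  perp <- c(-f$axis[2], f$axis[1])
  width <- extent_along(convex_hull(pts), perp)
  if (width <= 0) stop("degenerate (collinear) mask")
  list(lw_ratio = f$length_um / width, length_um = f$length_um,
       width_um = width, axis = f$axis)
}

#' Midline-relative orientation of an arbor
#'
#' The elongation axis is the max-Feret axis of the mask; the orientation is
#' the angle between that axis and the atlas midline axis, folded to
#' `[0, 90]` degrees (0 = parallel to the midline). Cells whose
#' length-to-width ratio is below `cfg$orientation_min_elongation` are
#' near-isotropic and get `NA` with `defined = FALSE`.
#'
#' @param arbor an `ArborMask`.
#' @param atlas a [region_atlas()] providing the midline axis.
#' @param cfg a [septastro_config()].
#' @param method `"feret"` (default) or `"pca"` (principal axis of the mask
#'   pixels, offered as an alternative estimator).
#' @return list: `orientation_deg` (NA when undefined), `defined`,
#'   `lw_ratio`.
#' @export
orientation_angle <- function(arbor, atlas, cfg = septastro_config(),
                              method = c("feret", "pca")) {
  method <- match.arg(method)
  lw <- length_width_ratio(arbor)
  if (lw$lw_ratio < cfg$orientation_min_elongation)
    return(list(orientation_deg = NA_real_, defined = FALSE,
                lw_ratio = lw$lw_ratio))
  axis <- if (method == "feret") lw$axis else {
    pix <- which(arbor$mask, arr.ind = TRUE)
    principal_axis((pix - 1) * rep(arbor$pixel_size_um, each = nrow(pix)))
  }
  list(orientation_deg = axis_angle_deg(axis, atlas$midline_axis),
       defined = TRUE, lw_ratio = lw$lw_ratio)
}

#' Bin orientation angles into fractions
#'
#' Fractions of defined-orientation cells per angle bin. Bins are half-open
#' `[a, b)` with the last bin closed; fractions sum to 1.
#'
#' @param angles_deg numeric angles in `[0, 90]`; NAs (undefined
#'   orientations) are dropped.
#' @param edges_deg strictly increasing bin edges spanning `[0, 90]`.
#' @return named numeric vector of fractions, one per bin.
#' @export
bin_angles <- function(angles_deg, edges_deg = c(0, 30, 60, 90)) {
  if (length(edges_deg) < 2 || any(diff(edges_deg) <= 0) ||
      edges_deg[1] != 0 || edges_deg[length(edges_deg)] != 90)
    stop("edges must be strictly increasing and span [0, 90]")
  a <- angles_deg[!is.na(angles_deg)]
  if (length(a) == 0) stop("no defined orientations to bin")
  if (any(a < 0 | a > 90)) stop("angles must lie in [0, 90]")
  nb <- length(edges_deg) - 1
  idx <- findInterval(a, edges_deg, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = nb)
  lab <- paste0("[", edges_deg[-length(edges_deg)], ",", edges_deg[-1],
                c(rep(")", nb - 1), "]"))
  stats::setNames(counts / length(a), lab)
}

#' Sholl profile of a skeleton
#'
#' Number of skeleton crossings of concentric circles around the nucleus at
#' radii `step_um, 2 step_um, ...` up to the longest branch. Crossings are
#' counted as circle-polyline segment intersections on the skeleton graph
#' edges.
#'
#' @param skel a `Skeleton`.
#' @param nucleus_yx_um circle centre; defaults to the stored nucleus.
#' @param step_um radius step, > 0.
#' @return data.frame: `radius_um`, `intersections`.
#' @export
sholl_profile <- function(skel, nucleus_yx_um = skel$nucleus_yx_um,
                          step_um = 5) {
  if (step_um <= 0) stop("step_um must be > 0")
  if (nrow(skel$pixels) == 0) stop("empty skeleton")
  rmax <- as.numeric(longest_branch(skel, nucleus_yx_um))
  radii <- seq(step_um, rmax, by = step_um)
  if (length(radii) == 0)
    return(data.frame(radius_um = numeric(0), intersections = integer(0)))
  counts <- integer(length(radii))
  for (e in skel$edges) {
    poly <- e$polyline_um
    if (nrow(poly) < 2) next
    d <- sqrt(rowSums(sweep(poly, 2, nucleus_yx_um)^2))
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      s <- d - r
      counts[ri] <- counts[ri] + sum(s[-length(s)] * s[-1] < 0) +
        sum(s == 0 & seq_along(s) > 1)
    }
  }
  data.frame(radius_um = radii, intersections = counts)
}

#' Full morphometry for one segmented astrocyte
#'
#' Convenience wrapper running skeletonization, territory, longest branch,
#' length-to-width ratio and orientation for one arbor, returning one flat
#' record (a row of the morphometry table).
#'
#' @param arbor an `ArborMask`.
#' @param atlas a [region_atlas()].
#' @param cfg a [septastro_config()].
#' @return one-row data.frame (`cell_id`, `longest_branch_um`, `lw_ratio`,
#'   `orientation_deg`, `orientation_defined`, `territory_area_um2`,
#'   `territory_volume_um3`, `border_touching`, `region_label`).
#' @export
measure_astrocyte <- function(arbor, atlas, cfg = septastro_config()) {
  skel <- skeletonize_arbor(arbor, cfg)
  terr <- compute_territory(arbor, cfg$stack_depth_um)
  lb <- longest_branch(skel)
  ori <- orientation_angle(arbor, atlas, cfg)
  cpx <- pmin(pmax(round(arbor$nucleus_yx_um / atlas$pixel_size_um) + 1, 1),
              dim(atlas$labels))
  code <- atlas$labels[cpx[1], cpx[2]]
  region <- if (code == 0) "outside" else
    names(atlas$label_map)[match(code, atlas$label_map)]
  data.frame(cell_id = arbor$cell_id,
             longest_branch_um = as.numeric(lb),
             longest_branch_fallback = attr(lb, "fallback"),
             lw_ratio = ori$lw_ratio,
             orientation_deg = ori$orientation_deg,
             orientation_defined = ori$defined,
             territory_area_um2 = terr$area_um2,
             territory_volume_um3 = terr$volume_um3,
             border_touching = arbor$border_touching,
             region_label = region)
}
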