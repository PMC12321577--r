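# Fluorescent puncta: 3-D spot detection, one-to-one pre/post
# colocalization, per-territory synapse density, puncta-per-nucleus, and
# MS-normalised regional density.

#' Detect sub-resolution puncta in 3-D
#'
#' Scale-normalised Laplacian-of-Gaussian detection at three scales
#' (`spot_sigma_um` +/- 50%), local maxima above `spot_min_response`
#' (robust automatic floor when `NULL`), sub-voxel centroid by per-axis
#' quadratic fit, and merging of duplicates within
#' `min_spot_separation_um`, keeping the stronger.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param cfg a [septastro_config()].
#' @return a `PunctaSet`: `channel`, `centroids_um` (n x 3 `(z, y, x)`),
#'   `response`, `scale_um`.
#' @export
detect_puncta <- function(stack, channel, cfg = septastro_config()) {
  arr <- get_channel(stack, channel)
  vox <- stack$voxel_size_um
  d <- dim(arr)
  scales <- cfg$spot_sigma_um * c(0.5, 1, 1.5)
  dets <- list()
  for (s in scales) {
    resp <- log_response(arr, s, vox)
    thr <- cfg$spot_min_response %||% auto_threshold(resp)
    pk <- local_maxima(resp, thr)
    if (nrow(pk) == 0) next
    cent <- matrix(0, nrow(pk), 3)
    for (i in seq_len(nrow(pk))) {
      p <- pk[i, ]
      off <- numeric(3)
      for (ax in 1:3) {
        if (d[ax] < 3 || p[ax] <= 1 || p[ax] >= d[ax]) next
        pm <- p; pm[ax] <- p[ax] - 1
        pp <- p; pp[ax] <- p[ax] + 1
        off[ax] <- quad_offset(resp[pm[1], pm[2], pm[3]],
                               resp[p[1], p[2], p[3]],
                               resp[pp[1], pp[2], pp[3]])
      }
      cent[i, ] <- (p - 1 + off) * vox
    }
    dets[[length(dets) + 1]] <- data.frame(
      z_um = cent[, 1], y_um = cent[, 2], x_um = cent[, 3],
      response = resp[pk], scale_um = s)
  }
  if (length(dets) == 0) {
    return(structure(list(channel = channel,
                          centroids_um = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("z_um", "y_um", "x_um"))),
                          response = numeric(0), scale_um = numeric(0)),
                     class = "PunctaSet"))
  }
  det <- do.call(rbind, dets)
  det <- det[order(-det$response, det$z_um, det$y_um, det$x_um), ]
  pts <- as.matrix(det[, c("z_um", "y_um", "x_um")])
  keep <- rep(TRUE, nrow(pts))
  min_sep <- cfg$min_spot_separation_um
  for (i in seq_len(nrow(pts))) {
    if (!keep[i] || i == nrow(pts)) next
    later <- which(keep)
    later <- later[later > i]
    if (length(later) == 0) break
    dd <- sqrt((pts[later, 1] - pts[i, 1])^2 + (pts[later, 2] - pts[i, 2])^2 +
               (pts[later, 3] - pts[i, 3])^2)
    keep[later[dd < min_sep]] <- FALSE
  }
  det <- det[keep, , drop = FALSE]
  ord <- order(det$z_um, det$y_um, det$x_um)
  det <- det[ord, , drop = FALSE]
  structure(list(channel = channel,
                 centroids_um = as.matrix(det[, c("z_um", "y_um", "x_um")]),
                 response = det$response, scale_um = det$scale_um),
            class = "PunctaSet")
}

#' Construct a PunctaSet from known centroids
#'
#' Wraps ground-truth or externally detected centroids in the container the
#' colocalization and density operators consume.
#' @param centroids_um n x 3 `(z, y, x)` micrometre positions.
#' @param channel channel name.
#' @return a `PunctaSet`.
#' @export
puncta_set <- function(centroids_um, channel = "spots") {
  centroids_um <- as.matrix(centroids_um)
  if (ncol(centroids_um) != 3) stop("centroids must be n x 3 (z, y, x)")
  colnames(centroids_um) <- c("z_um", "y_um", "x_um")
  structure(list(channel = channel, centroids_um = centroids_um,
                 response = rep(NA_real_, nrow(centroids_um)),
                 scale_um = rep(NA_real_, nrow(centroids_um))),
            class = "PunctaSet")
}

#' Colocalize two puncta channels
#'
#' Greedy globally-nearest one-to-one matching: repeatedly pair the closest
#' unmatched (pre, post) couple with distance <= `max_dist_um`; ties broken
#' by (pre_id, post_id) lexicographic order. One-to-one matching prevents a
#' single postsynaptic punctum apposed to several presynaptic puncta from
#' being counted as several synapses.
#'
#' @param pre,post `PunctaSet`s (see [detect_puncta()], [puncta_set()]).
#' @param max_dist_um maximum pairing distance, > 0.
#' @return a `ColocPairs`: data.frame `pre_id`, `post_id`, `distance_um`
#'   (possibly zero rows), with attributes `n_pre`, `n_post`.
#' @export
colocalize <- function(pre, post, max_dist_um = 0.5) {
  if (max_dist_um <= 0) stop("max_dist_um must be > 0")
  A <- pre$centroids_um; B <- post$centroids_um
  empty <- data.frame(pre_id = integer(0), post_id = integer(0),
                      distance_um = numeric(0))
  if (nrow(A) == 0 || nrow(B) == 0) {
    attr(empty, "n_pre") <- nrow(A); attr(empty, "n_post") <- nrow(B)
    class(empty) <- c("ColocPairs", "data.frame")
    return(empty)
  }
  # candidate pairs within max_dist (block over pre to bound memory)
  cand <- list()
  bs <- max(1L, floor(5e6 / max(1, nrow(B))))
  for (st in seq(1, nrow(A), by = bs)) {
    ii <- st:min(nrow(A), st + bs - 1)
    d2 <- outer(A[ii, 1], B[, 1], `-`)^2 + outer(A[ii, 2], B[, 2], `-`)^2 +
          outer(A[ii, 3], B[, 3], `-`)^2
    hit <- which(d2 <= max_dist_um^2, arr.ind = TRUE)
    if (nrow(hit) > 0)
      cand[[length(cand) + 1]] <- data.frame(pre_id = ii[hit[, 1]],
                                             post_id = hit[, 2],
                                             distance_um = sqrt(d2[hit]))
  }
  if (length(cand) == 0) {
    attr(empty, "n_pre") <- nrow(A); attr(empty, "n_post") <- nrow(B)
    class(empty) <- c("ColocPairs", "data.frame")
    return(empty)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$distance_um, cand$pre_id, cand$post_id), ]
  used_pre <- logical(nrow(A)); used_post <- logical(nrow(B))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$pre_id[i]; q <- cand$post_id[i]
    if (!used_pre[p] && !used_post[q]) {
      keep[i] <- TRUE
      used_pre[p] <- TRUE; used_post[q] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pre") <- nrow(A); attr(out, "n_post") <- nrow(B)
  class(out) <- c("ColocPairs", "data.frame")
  out
}

#' Synapse density within an astrocyte territory
#'
#' Counts colocalized pairs whose centroid midpoint falls inside the
#' territory polygon (2-D test on `(y, x)`; any z within the stack depth is
#' accepted) and reports the density per cubic millimetre.
#'
#' @param pairs a `ColocPairs` from [colocalize()].
#' @param pre,post the matched `PunctaSet`s (for midpoint positions).
#' @param territory a `Territory` from [compute_territory()].
#' @return data.frame: `cell_id`, `n_coloc`, `territory_volume_um3`,
#'   `density_per_mm3`.
#' @export
territory_synapse_density <- function(pairs, pre, post, territory) {
  if (territory$volume_um3 <= 0) stop("territory volume must be > 0")
  n <- 0L
  if (nrow(pairs) > 0) {
    mid <- (pre$centroids_um[pairs$pre_id, , drop = FALSE] +
            post$centroids_um[pairs$post_id, , drop = FALSE]) / 2
    inside <- points_in_polygon(mid[, c("y_um", "x_um"), drop = FALSE],
                                territory$polygon_um)
    n <- sum(inside)
  }
  data.frame(cell_id = territory$cell_id, n_coloc = n,
             territory_volume_um3 = territory$volume_um3,
             density_per_mm3 = n / (territory$volume_um3 * 1e-9))
}

#' Assign puncta to nuclei and count per nucleus
#'
#' A punctum belongs to a nucleus when its projected `(y, x)` centroid lies
#' in that nuclear mask dilated by `margin_um`; a punctum inside two dilated
#' masks goes to the nucleus with the nearer centroid, ties to the smaller
#' nucleus id.
#'
#' @param spots a `PunctaSet`.
#' @param nuclei a `NucleusSet` (label grid + centroids).
#' @param margin_um dilation margin in micrometres (default 0).
#' @return data.frame: `nucleus_id`, `count`.
#' @export
puncta_per_nucleus <- function(spots, nuclei, margin_um = 0) {
  n_nuc <- nrow(nuclei$centroids_um)
  if (n_nuc == 0) stop("empty nucleus set")
  px <- nuclei$pixel_size_um
  counts <- integer(n_nuc)
  pts <- spots$centroids_um[, c("y_um", "x_um"), drop = FALSE]
  lab <- nuclei$labels
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    ppx <- round(p / px) + 1
    direct <- if (ppx[1] >= 1 && ppx[1] <= nrow(lab) &&
                  ppx[2] >= 1 && ppx[2] <= ncol(lab)) lab[ppx[1], ppx[2]] else 0L
    if (margin_um <= 0) {
      if (direct > 0) counts[direct] <- counts[direct] + 1L
      next
    }
    # candidates: nuclei whose centroid could be within reach
    reach <- max(nuclei$radii_um) + margin_um + max(px)
    dc <- sqrt((nuclei$centroids_um[, 1] - p[1])^2 +
               (nuclei$centroids_um[, 2] - p[2])^2)
    cands <- which(dc <= reach)
    hits <- integer(0)
    for (j in cands) {
      mpix <- which(lab == j, arr.ind = TRUE)
      if (nrow(mpix) == 0) next
      dmin <- min(sqrt(((mpix[, 1] - 1) * px[1] - p[1])^2 +
                       ((mpix[, 2] - 1) * px[2] - p[2])^2))
      if (dmin <= margin_um || (direct == j)) hits <- c(hits, j)
    }
    if (length(hits) == 0) next
    if (length(hits) > 1) {
      dd <- dc[hits]
      hits <- hits[order(dd, hits)]   # nearer centroid, then smaller id
    }
    counts[hits[1]] <- counts[hits[1]] + 1L
  }
  data.frame(nucleus_id = seq_len(n_nuc), count = counts)
}

#' Regional puncta density normalised to the MS
#'
#' Per-region 2-D density of projected puncta centroids (count / region
#' area), each reported relative to the MS density — the regional
#' transcript-density heatmap convention.
#'
#' @param spots a `PunctaSet`.
#' @param atlas a [region_atlas()]; the MS must be nonempty with density
#'   > 0, otherwise the normalisation is undefined.
#' @return data.frame: `region_label`, `count`, `area_um2`,
#'   `density_per_um2`, `relative_to_MS`.
#' @export
regional_relative_density <- function(spots, atlas) {
  regions <- atlas_regions(atlas)
  if (!"MS" %in% regions) stop("normalization undefined: MS region empty")
  pts <- spots$centroids_um[, c("y_um", "x_um"), drop = FALSE]
  px <- atlas$pixel_size_um
  ppx <- round(sweep(pts, 2, px, `/`)) + 1
  inb <- ppx[, 1] >= 1 & ppx[, 1] <= nrow(atlas$labels) &
         ppx[, 2] >= 1 & ppx[, 2] <= ncol(atlas$labels)
  codes <- rep(0L, nrow(ppx))
  codes[inb] <- atlas$labels[ppx[inb, , drop = FALSE]]
  out <- do.call(rbind, lapply(regions, function(rg) {
    code <- atlas$label_map[[rg]]
    area <- region_area_um2(atlas, rg)
    cnt <- sum(codes == code)
    data.frame(region_label = rg, count = cnt, area_um2 = area,
               density_per_um2 = cnt / area)
  }))
  ms <- out$density_per_um2[out$region_label == "MS"]
  if (ms <= 0) stop("normalization undefined: MS density is 0")
  out$relative_to_MS <- out$density_per_um2 / ms
  out
}
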