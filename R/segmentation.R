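# Segmentation of sparse-labelled astrocytes: nucleus detection on the
# DAPI channel, reporter-channel arbor masks, topological skeletonization
# (replacing interactive filament tracing), and convex-hull territories.

#' Detect nuclei in a stack channel
#'
#' Scale-normalised Laplacian-of-Gaussian blob detection on the maximum
#' projection, at three scales around half the nominal nuclear radius.
#' Centroids are refined by intensity-weighted centre of mass in a local
#' window; each nuclear mask is the Otsu-thresholded region within twice
#' the detected radius.
#'
#' @param stack an [image_stack()].
#' @param channel channel name (typically `"DAPI"`).
#' @param cfg a [septastro_config()]; uses `nucleus_radius_um` and
#'   `nucleus_min_response` (`NULL` = robust automatic floor).
#' @return a `NucleusSet`: `centroids_um` (n x 2 `(y, x)`), `radii_um`,
#'   `labels` (integer mask grid, labels dense 1..n), `pixel_size_um`.
#' @export
detect_nuclei <- function(stack, channel, cfg = septastro_config()) {
  proj <- max_project(stack, channel)
  px <- stack$voxel_size_um[2:3]
  sigma0 <- cfg$nucleus_radius_um / 2
  arr <- array(proj, dim = c(1, nrow(proj), ncol(proj)))
  vox <- c(1, px)
  best <- NULL
  for (s in sigma0 * c(0.75, 1, 1.25)) {
    resp <- log_response(arr, s, vox)
    if (is.null(best)) best <- resp else best <- pmax(best, resp)
  }
  # nuclei are bright extended blobs: the LoG response pools many voxels,
  # so a higher floor than for sub-resolution spots rejects noise outright
  thr <- cfg$nucleus_min_response %||%
    (stats::median(best) + 10 * stats::mad(best))
  pk <- local_maxima(best, thr)
  if (nrow(pk) == 0)
    return(structure(list(centroids_um = matrix(numeric(0), 0, 2),
                          radii_um = numeric(0),
                          labels = matrix(0L, nrow(proj), ncol(proj)),
                          pixel_size_um = px), class = "NucleusSet"))
  # merge peaks closer than one nuclear radius, keeping the stronger
  vals <- best[pk]
  ord <- order(-vals, pk[, 2], pk[, 3])
  pk <- pk[ord, , drop = FALSE]
  pos_um <- cbind((pk[, 2] - 1) * px[1], (pk[, 3] - 1) * px[2])
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      later <- (i + 1):nrow(pk)
      d <- sqrt((pos_um[later, 1] - pos_um[i, 1])^2 +
                (pos_um[later, 2] - pos_um[i, 2])^2)
      keep[later][d < cfg$nucleus_radius_um] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  # intensity-weighted centre-of-mass refinement
  r_px <- pmax(1, round(cfg$nucleus_radius_um / px))
  cent <- matrix(0, nrow(pk), 2)
  for (i in seq_len(nrow(pk))) {
    yi <- max(1, pk[i, 2] - r_px[1]):min(nrow(proj), pk[i, 2] + r_px[1])
    xi <- max(1, pk[i, 3] - r_px[2]):min(ncol(proj), pk[i, 3] + r_px[2])
    w <- proj[yi, xi, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) w[] <- 1
    cent[i, ] <- c(sum((yi - 1) * rowSums(w)) / sum(w) * px[1],
                   sum((xi - 1) * colSums(w)) / sum(w) * px[2])
  }
  # deterministic ordering, labels dense 1..n
  ord2 <- order(cent[, 1], cent[, 2])
  cent <- cent[ord2, , drop = FALSE]
  colnames(cent) <- c("y_um", "x_um")
  labels <- matrix(0L, nrow(proj), ncol(proj))
  r2_px <- pmax(1, round(2 * cfg$nucleus_radius_um / px))
  for (i in seq_len(nrow(cent))) {
    cpx <- round(cent[i, ] / px) + 1
    yi <- max(1, cpx[1] - r2_px[1]):min(nrow(proj), cpx[1] + r2_px[1])
    xi <- max(1, cpx[2] - r2_px[2]):min(ncol(proj), cpx[2] + r2_px[2])
    w <- proj[yi, xi, drop = FALSE]
    rng <- range(w)
    if (diff(rng) <= 0) next
    thr_o <- EBImage::otsu((w - rng[1]) / diff(rng)) * diff(rng) + rng[1]
    sub <- w > thr_o
    # restrict to the disc of 2 radii around the centroid
    dy <- (yi - 1) * px[1] - cent[i, 1]
    dx <- (xi - 1) * px[2] - cent[i, 2]
    sub <- sub & outer(dy^2, dx^2, `+`) <= (2 * cfg$nucleus_radius_um)^2
    labels[yi, xi][sub & labels[yi, xi] == 0L] <- i
  }
  structure(list(centroids_um = cent,
                 radii_um = rep(cfg$nucleus_radius_um, nrow(cent)),
                 labels = labels, pixel_size_um = px),
            class = "NucleusSet")
}

#' Segment one sparse-labelled astrocyte arbor
#'
#' Max-projects the reporter channel, thresholds it (Otsu within a window
#' around the nucleus, or the fixed `arbor_threshold` when set — Otsu is
#' degenerate on two-valued noise-free images), keeps the connected
#' component containing the nucleus centroid, and fills holes.
#'
#' @param stack an [image_stack()].
#' @param channel reporter channel name.
#' @param nucleus_yx_um nucleus centroid `(y, x)` in micrometres.
#' @param cfg a [septastro_config()].
#' @return an `ArborMask`: `cell_id` (NA until assigned), `mask` (logical
#'   matrix), `nucleus_yx_um`, `pixel_size_um`, `border_touching`.
#' @export
segment_arbor <- function(stack, channel, nucleus_yx_um,
                          cfg = septastro_config()) {
  proj <- max_project(stack, channel)
  px <- stack$voxel_size_um[2:3]
  cpx <- round(nucleus_yx_um / px) + 1
  if (cpx[1] < 1 || cpx[1] > nrow(proj) || cpx[2] < 1 || cpx[2] > ncol(proj))
    stop("nucleus centroid outside image bounds")
  if (!is.null(cfg$arbor_threshold)) {
    thr <- cfg$arbor_threshold
  } else {
    w_px <- round(cfg$arbor_window_um / px)
    yi <- max(1, cpx[1] - w_px[1]):min(nrow(proj), cpx[1] + w_px[1])
    xi <- max(1, cpx[2] - w_px[2]):min(ncol(proj), cpx[2] + w_px[2])
    w <- proj[yi, xi, drop = FALSE]
    rng <- range(w)
    if (diff(rng) <= 0) stop("no arbor found: flat window around nucleus")
    thr <- EBImage::otsu((w - rng[1]) / diff(rng), levels = 256) *
      diff(rng) + rng[1]
  }
  bin <- proj > thr
  if (!bin[cpx[1], cpx[2]]) {
    # tolerate a nucleus centroid a voxel off the arbor: look in a small disc
    r <- 3
    yi <- max(1, cpx[1] - r):min(nrow(proj), cpx[1] + r)
    xi <- max(1, cpx[2] - r):min(ncol(proj), cpx[2] + r)
    hit <- which(bin[yi, xi, drop = FALSE], arr.ind = TRUE)
    if (nrow(hit) == 0) stop("no arbor found at nucleus centroid")
    cpx <- c(yi[hit[1, 1]], xi[hit[1, 2]])
  }
  lab <- EBImage::bwlabel(bin)
  id <- lab[cpx[1], cpx[2]]
  mask <- lab == id
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  structure(list(cell_id = NA_integer_, mask = mask,
                 nucleus_yx_um = as.numeric(nucleus_yx_um),
                 pixel_size_um = px, border_touching = border),
            class = "ArborMask")
}

# ---- skeletonization ------------------------------------------------------

# one Zhang-Suen subiteration; m is 0/1 integer matrix, returns updated m
zs_subiter <- function(m, first) {
  ny <- nrow(m); nx <- ncol(m)
  p <- matrix(0L, ny + 2, nx + 2)
  p[2:(ny + 1), 2:(nx + 1)] <- m
  sh <- function(dy, dx) p[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
  P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
  P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
       (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
       (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
  if (first) {
    cond <- (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  } else {
    cond <- (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  }
  del <- m == 1L & B >= 2 & B <= 6 & A == 1 & cond
  m[del] <- 0L
  m
}

# Zhang-Suen topological thinning of a logical matrix (cropped to the
# mask bounding box for speed)
thin_mask <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) return(mask)
  y0 <- max(1, min(pix[, 1]) - 1); y1 <- min(nrow(mask), max(pix[, 1]) + 1)
  x0 <- max(1, min(pix[, 2]) - 1); x1 <- min(ncol(mask), max(pix[, 2]) + 1)
  m <- matrix(as.integer(mask[y0:y1, x0:x1]), y1 - y0 + 1, x1 - x0 + 1)
  repeat {
    m1 <- zs_subiter(m, TRUE)
    m2 <- zs_subiter(m1, FALSE)
    if (identical(m2, m)) break
    m <- m2
  }
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[y0:y1, x0:x1] <- m == 1L
  out
}

# build a node/edge graph from a skeleton pixel set. Adjacency is
# 8-connectivity with corner suppression: a diagonal edge exists only when
# neither shared cardinal neighbour is itself a skeleton pixel, which
# removes the staircase corner artifacts of thinning.
skeleton_graph <- function(skel, pixel_size_um) {
  pix <- which(skel, arr.ind = TRUE)
  n <- nrow(pix)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[pix] <- seq_len(n)
  at <- function(y, x) {
    if (y >= 1 && y <= nrow(skel) && x >= 1 && x <= ncol(skel)) id[y, x]
    else 0L
  }
  nbrs <- function(i) {
    y <- pix[i, 1]; x <- pix[i, 2]
    out <- integer(0)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      q <- at(y + dy, x + dx)
      if (q == 0L) next
      if (dy != 0 && dx != 0 &&
          (at(y + dy, x) > 0L || at(y, x + dx) > 0L)) next
      out <- c(out, q)
    }
    out
  }
  adj <- lapply(seq_len(n), nbrs)
  deg <- lengths(adj)
  nodes <- which(deg != 2)
  if (length(nodes) == 0 && n > 0) nodes <- 1L  # pure cycle
  is_node <- rep(FALSE, n); is_node[nodes] <- TRUE
  edges <- list()
  used <- new.env(hash = TRUE)
  step_key <- function(a, b) paste0(min(a, b), "-", max(a, b))
  for (v in nodes) {
    for (w in adj[[v]]) {
      k <- step_key(v, w)
      if (!is.null(used[[k]])) next
      path <- c(v, w)
      used[[k]] <- TRUE
      prev <- v; cur <- w
      while (!is_node[cur]) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        used[[step_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      poly <- (pix[path, , drop = FALSE] - 1) *
        rep(pixel_size_um, each = length(path))
      seglen <- if (length(path) > 1)
        sum(sqrt(rowSums(diff(poly)^2))) else 0
      edges[[length(edges) + 1]] <- list(from = path[1],
                                         to = path[length(path)],
                                         path_idx = path,
                                         polyline_um = poly,
                                         length_um = seglen)
    }
  }
  list(pix = pix, id = id, adj = adj, deg = deg, nodes = nodes, edges = edges)
}

#' Skeletonize an arbor mask
#'
#' 2-D topological thinning (Zhang-Suen) of the arbor mask, followed by
#' pruning of spurs shorter than `cfg$min_spur_um` (thinning artifacts at
#' synthetic scales) and construction of a node/edge graph with polyline
#' edge lengths in micrometres.
#'
#' @param arbor an `ArborMask` from [segment_arbor()].
#' @param cfg a [septastro_config()].
#' @return a `Skeleton`: `cell_id`, `pixels` (n x 2 1-based indices),
#'   `endpoints_um` (m x 2 `(y, x)` micrometres), `edges` (list with
#'   `polyline_um` and `length_um`), `total_length_um`, `pixel_size_um`.
#' @export
skeletonize_arbor <- function(arbor, cfg = septastro_config()) {
  if (!any(arbor$mask)) stop("empty arbor mask")
  px <- arbor$pixel_size_um
  skel <- thin_mask(arbor$mask)
  # iterative spur pruning
  repeat {
    g <- skeleton_graph(skel, px)
    if (length(g$edges) <= 1) break
    endpoints <- which(g$deg == 1)
    pruned <- FALSE
    for (e in g$edges) {
      tips <- c(e$from, e$to)
      tip_end <- tips[g$deg[tips] == 1]
      other <- tips[g$deg[tips] > 2]
      if (length(tip_end) >= 1 && length(other) >= 1 &&
          e$length_um < cfg$min_spur_um) {
        drop_idx <- setdiff(e$path_idx, other)
        skel[g$pix[drop_idx, , drop = FALSE]] <- FALSE
        pruned <- TRUE
      }
    }
    if (!pruned) break
    skel <- thin_mask(skel)   # clean residual junction stubs
  }
  g <- skeleton_graph(skel, px)
  ep <- which(g$deg == 1)
  ep_um <- (g$pix[ep, , drop = FALSE] - 1) * rep(px, each = length(ep))
  colnames(ep_um) <- c("y_um", "x_um")
  structure(list(cell_id = arbor$cell_id, pixels = g$pix,
                 endpoints_um = ep_um, edges = g$edges,
                 total_length_um = sum(vapply(g$edges, `[[`, numeric(1),
                                              "length_um")),
                 nucleus_yx_um = arbor$nucleus_yx_um,
                 pixel_size_um = px),
            class = "Skeleton")
}

#' Compute the territory of an arbor
#'
#' The astrocyte territory is the convex hull of the arbor mask pixel
#' centres, in micrometres; its volume is area times the stack depth.
#'
#' @param arbor an `ArborMask`.
#' @param depth_um stack depth used for the volume (default 5).
#' @return a `Territory`: `cell_id`, `polygon_um` (hull vertices, (y, x)),
#'   `area_um2`, `volume_um3`.
#' @export
compute_territory <- function(arbor, depth_um = 5) {
  pix <- which(arbor$mask, arr.ind = TRUE)
  if (nrow(pix) == 0) stop("empty arbor mask")
  pts <- (pix - 1) * rep(arbor$pixel_size_um, each = nrow(pix))
  hull <- convex_hull(pts)
  area <- polygon_area(hull)
  if (area <= 0) stop("degenerate (collinear) arbor mask")
  structure(list(cell_id = arbor$cell_id, polygon_um = hull,
                 area_um2 = area, volume_um3 = area * depth_um),
            class = "Territory")
}
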