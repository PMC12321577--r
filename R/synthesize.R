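# Ground-truth simulator: septal atlas presets, star-shaped astrocyte
# arbors with von Mises branch orientations, Gaussian-PSF rendering,
# Poisson puncta fields with a controllable truly-colocalized fraction,
# and two-marker lineage mosaics. Every stochastic output is exactly
# reproducible from (seed, config); per-cell draws use counter-based
# substreams so adding a cell never perturbs the others.

#' Build a preset septal region atlas
#'
#' Deterministic rectangular layout: the MS occupies a medial column along
#' the vertical midline (left quarter of the field) and the LS subdivisions
#' dLS, iLS, vLS are stacked dorsoventrally in the lateral part. The midline
#' axis is dorsoventral, `(y, x) = (1, 0)`.
#'
#' @param shape_yx integer `(ny, nx)`, both >= 64.
#' @param layout preset name; only `"default"` is defined.
#' @param pixel_size_um `(y, x)` micrometres per pixel.
#' @return a [region_atlas()] with every pixel labelled.
#' @export
make_atlas <- function(shape_yx, layout = "default",
                       pixel_size_um = c(0.2, 0.2)) {
  if (any(shape_yx < 64)) stop("atlas shape must be at least 64 x 64")
  if (!identical(layout, "default")) stop("unknown atlas preset: ", layout)
  ny <- shape_yx[1]; nx <- shape_yx[2]
  labels <- matrix(0L, ny, nx)
  ms_w <- floor(nx / 4)
  labels[, seq_len(ms_w)] <- 1L                      # MS: medial column
  thirds <- round(c(0, ny / 3, 2 * ny / 3, ny))
  lat <- (ms_w + 1):nx
  labels[(thirds[1] + 1):thirds[2], lat] <- 2L       # dLS
  labels[(thirds[2] + 1):thirds[3], lat] <- 3L       # iLS
  labels[(thirds[3] + 1):thirds[4], lat] <- 4L       # vLS
  region_atlas(labels, midline_axis = c(1, 0), pixel_size_um = pixel_size_um)
}

#' Sample one ground-truth astrocyte arbor
#'
#' Branch directions are von Mises about `orientation_mu_deg` (measured from
#' the midline axis, by convention the image y axis) with concentration
#' `orientation_kappa`; `kappa = 0` gives the isotropic LS-like case and
#' large kappa the midline-aligned MS-like case. Branch lengths are
#' Normal(mean, sd) truncated at > 1 um. Uses the current RNG state.
#'
#' @param cfg a [synth_config()].
#' @param soma_yx_um soma position `(y, x)` in micrometres.
#' @param cell_id integer id recorded in the record.
#' @return a `GroundTruthCell` list: `cell_id`, `soma_yx_um`, `tips_um`
#'   (n x 2), `branch_lengths_um`, `branch_angles_deg` (folded to [0, 90]),
#'   `true_longest_branch_um`, `true_orientation_deg`, `region_label`,
#'   `markers`.
#' @export
sample_arbor <- function(cfg, soma_yx_um, cell_id = 1L) {
  if (cfg$n_branches < 2) stop("n_branches must be >= 2")
  if (cfg$branch_length_mean_um <= 0) stop("branch length mean must be > 0")
  nb <- cfg$n_branches
  mu <- cfg$orientation_mu_deg * pi / 180
  theta <- rvonmises(nb, mu, cfg$orientation_kappa)
  if (cfg$branch_length_sd_um == 0) {
    len <- rep(cfg$branch_length_mean_um, nb)
  } else {
    len <- numeric(0)
    while (length(len) < nb) {
      draw <- stats::rnorm(nb, cfg$branch_length_mean_um,
                           cfg$branch_length_sd_um)
      len <- c(len, draw[draw > 1])
    }
    len <- len[seq_len(nb)]
  }
  # theta = 0 points along the midline (+y)
  dirs <- cbind(cos(theta), sin(theta))
  tips <- sweep(dirs * len, 2, soma_yx_um, `+`)
  colnames(tips) <- c("y_um", "x_um")
  ref <- if (nb >= 2) principal_axis(tips) else dirs[1, ]
  cell <- list(
    cell_id = as.integer(cell_id),
    soma_yx_um = as.numeric(soma_yx_um),
    tips_um = tips,
    branch_lengths_um = len,
    branch_angles_deg = fold_angle_deg(theta * 180 / pi),
    true_longest_branch_um = max(sqrt(rowSums(sweep(tips, 2, soma_yx_um)^2))),
    true_orientation_deg = axis_angle_deg(ref, c(1, 0)),
    region_label = NA_character_,
    markers = list()
  )
  class(cell) <- "GroundTruthCell"
  cell
}

# rasterize a segment onto a (y, x) pixel grid; returns unique pixel index
# matrix (row = y, col = x), 1-based
raster_segment <- function(a_um, b_um, pixel_size_um, ny, nx) {
  len_px <- sqrt(sum(((b_um - a_um) / pixel_size_um)^2))
  n <- max(2L, ceiling(len_px * 2) + 1L)
  t <- seq(0, 1, length.out = n)
  y <- round(a_um[1] / pixel_size_um[1] * (1 - t) + b_um[1] / pixel_size_um[1] * t) + 1
  x <- round(a_um[2] / pixel_size_um[2] * (1 - t) + b_um[2] / pixel_size_um[2] * t) + 1
  keep <- y >= 1 & y <= ny & x >= 1 & x <= nx
  unique(cbind(y[keep], x[keep]))
}

#' Render ground-truth cells into a multichannel z-stack
#'
#' Channels produced: `DAPI` (Gaussian nuclei at the somata, sigma = half
#' the nuclear radius), the reporter channel `tdT` (branches rasterized as
#' lines of width `branch_width_um`, placed in the central z-plane, then
#' blurred with the Gaussian PSF), and one nuclear channel per marker name
#' found in the cells' `markers` maps, rendered only where the cell is
#' flagged positive. Background level and Gaussian noise are added to every
#' channel (noise uses the current RNG state; pass `noise_sd = 0` in the
#' config for a deterministic image).
#'
#' @param cells list of `GroundTruthCell`s; somata must be pairwise farther
#'   apart than twice the nuclear radius.
#' @param cfg a [synth_config()].
#' @param shape_yx image shape in pixels; defaults to the atlas shape.
#' @param atlas optional [region_atlas()] fixing the shape and pixel size.
#' @return an [image_stack()].
#' @export
render_cells <- function(cells, cfg, shape_yx = NULL, atlas = NULL) {
  vox <- cfg$voxel_size_um
  if (!is.null(atlas)) {
    shape_yx <- dim(atlas$labels)
    vox <- c(vox[1], atlas$pixel_size_um)
  }
  if (is.null(shape_yx)) stop("shape_yx or atlas required")
  ny <- shape_yx[1]; nx <- shape_yx[2]; nz <- cfg$n_z
  somata <- do.call(rbind, lapply(cells, `[[`, "soma_yx_um"))
  if (length(cells) > 1) {
    d <- as.matrix(stats::dist(somata))
    diag(d) <- Inf
    coll <- which(d < 2 * cfg$nucleus_radius_um, arr.ind = TRUE)
    if (nrow(coll) > 0) {
      ids <- vapply(cells, `[[`, integer(1), "cell_id")
      bad <- unique(t(apply(coll, 1, sort)))
      stop("somata closer than twice the nuclear radius: ",
           paste(apply(bad, 1, function(p)
             paste0("(", ids[p[1]], ",", ids[p[2]], ")")), collapse = " "))
    }
  }
  marker_names <- sort(unique(unlist(lapply(cells, function(cl)
    names(cl$markers)))))
  channels <- c("DAPI", "tdT", marker_names)
  voxels <- array(0, dim = c(length(channels), nz, ny, nx))

  nuc_sigma <- cfg$nucleus_radius_um / 2
  zc <- (nz - 1) / 2   # central z index (0-based)
  gauss2d <- function(center_yx_um, sigma_um, amp) {
    ry <- ceiling(4 * sigma_um / vox[2]); rx <- ceiling(4 * sigma_um / vox[3])
    cyi <- round(center_yx_um[1] / vox[2]); cxi <- round(center_yx_um[2] / vox[3])
    yi <- max(0, cyi - ry):min(ny - 1, cyi + ry)
    xi <- max(0, cxi - rx):min(nx - 1, cxi + rx)
    if (length(yi) == 0 || length(xi) == 0) return(NULL)
    dy <- yi * vox[2] - center_yx_um[1]
    dx <- xi * vox[3] - center_yx_um[2]
    g <- outer(exp(-dy^2 / (2 * sigma_um^2)), exp(-dx^2 / (2 * sigma_um^2)))
    list(yi = yi + 1, xi = xi + 1, g = amp * g)
  }
  add_nuclear <- function(ch, center, amp) {
    p <- gauss2d(center, nuc_sigma, amp)
    if (is.null(p)) return()
    for (zi in seq_len(nz)) {
      zfac <- exp(-((zi - 1 - zc) * vox[1])^2 / (2 * nuc_sigma^2))
      voxels[ch, zi, p$yi, p$xi] <<- voxels[ch, zi, p$yi, p$xi] + zfac * p$g
    }
  }

  # reporter: rasterize all branches into a 2-D support mask
  support <- matrix(0, ny, nx)
  for (cl in cells) {
    for (b in seq_len(nrow(cl$tips_um))) {
      px <- raster_segment(cl$soma_yx_um, cl$tips_um[b, ], vox[2:3], ny, nx)
      support[px] <- 1
    }
  }
  w_px <- max(1, round(cfg$branch_width_um / vox[2]))
  if (w_px > 1) {
    brush <- EBImage::makeBrush(if (w_px %% 2 == 1) w_px else w_px + 1,
                                shape = "disc")
    support <- as.matrix(EBImage::dilate(support, brush))
  }
  rep_ch <- match("tdT", channels)
  mid_z <- floor(nz / 2) + 1
  voxels[rep_ch, mid_z, , ] <- support * cfg$amplitude

  for (cl in cells) {
    add_nuclear(match("DAPI", channels), cl$soma_yx_um, cfg$amplitude)
    for (mk in names(cl$markers))
      if (isTRUE(cl$markers[[mk]]))
        add_nuclear(match(mk, channels), cl$soma_yx_um, cfg$amplitude)
  }

  # PSF blur on the reporter channel (nuclei are already Gaussian)
  if (cfg$psf_sigma_um > 0) {
    arr <- voxels[rep_ch, , , ]
    dim(arr) <- c(nz, ny, nx)
    voxels[rep_ch, , , ] <- gauss_smooth(arr, cfg$psf_sigma_um, vox)
  }

  voxels <- voxels + cfg$background_level
  if (cfg$noise_sd > 0)
    voxels <- voxels + stats::rnorm(length(voxels), 0, cfg$noise_sd)
  voxels[voxels < 0] <- 0
  image_stack(voxels, vox, channels)
}

#' Sample ground-truth pre/post puncta in a box
#'
#' Presynaptic centroids follow a homogeneous Poisson process at
#' `lambda_pre_per_um3`. A fraction `coloc_fraction` of them receives a
#' paired postsynaptic punctum displaced uniformly within a ball of radius
#' `coloc_radius_um`; the remaining postsynaptic puncta are an independent
#' Poisson process at `lambda_post_per_um3`. Uses the current RNG state.
#'
#' @param cfg a [synth_config()].
#' @param box_um `(z, y, x)` box dimensions in micrometres (volume > 0).
#' @return a `GroundTruthPuncta` list: `pre_um`, `post_um` (n x 3 `(z,y,x)`
#'   matrices), `coloc_pairs` (two-column matrix of 1-based pre/post ids),
#'   and `box_um`.
#' @export
sample_puncta <- function(cfg, box_um) {
  vol <- prod(box_um)
  if (vol <= 0) stop("box volume must be > 0")
  if (cfg$coloc_fraction > 0 && cfg$coloc_radius_um <= 0)
    stop("coloc_radius_um must be > 0 when coloc_fraction > 0")
  runif_box <- function(n) cbind(stats::runif(n, 0, box_um[1]),
                                 stats::runif(n, 0, box_um[2]),
                                 stats::runif(n, 0, box_um[3]))
  n_pre <- stats::rpois(1, cfg$lambda_pre_per_um3 * vol)
  pre <- runif_box(n_pre)
  colnames(pre) <- c("z_um", "y_um", "x_um")
  n_coloc <- stats::rbinom(1, n_pre, cfg$coloc_fraction)
  paired_pre <- if (n_pre > 0) sort(sample.int(n_pre, n_coloc)) else integer(0)
  # uniform displacement within a ball of radius coloc_radius_um
  disp <- matrix(0, n_coloc, 3)
  if (n_coloc > 0) {
    u <- matrix(stats::rnorm(3 * n_coloc), n_coloc, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- cfg$coloc_radius_um * stats::runif(n_coloc)^(1 / 3)
    disp <- u * r
  }
  post_paired <- pre[paired_pre, , drop = FALSE] + disp
  n_extra <- stats::rpois(1, cfg$lambda_post_per_um3 * vol)
  post <- rbind(post_paired, runif_box(n_extra))
  colnames(post) <- c("z_um", "y_um", "x_um")
  pairs <- cbind(pre_id = paired_pre, post_id = seq_len(n_coloc))
  structure(list(pre_um = pre, post_um = post,
                 coloc_pairs = pairs, box_um = as.numeric(box_um)),
            class = "GroundTruthPuncta")
}

#' Render point spots into a single-channel z-stack
#'
#' Each centroid becomes a 3-D Gaussian of sigma `cfg$spot_sigma_um` and
#' peak `cfg$amplitude` over `cfg$background_level` plus Gaussian noise
#' (current RNG state). Laterally the Gaussian is evaluated at voxel
#' centres; axially, where z sampling is much coarser than the spot, each
#' slice receives the Gaussian mass integrated over its depth (the
#' optical-section integration of a confocal voxel), so a sub-resolution
#' spot never falls invisibly between slices.
#'
#' @param centroids_um n x 3 `(z, y, x)` micrometre positions.
#' @param cfg a [synth_config()].
#' @param shape_zyx image shape in voxels `(z, y, x)`.
#' @param channel channel name for the resulting stack.
#' @return an [image_stack()] with one channel.
#' @export
render_puncta <- function(centroids_um, cfg, shape_zyx, channel = "pre") {
  vox <- cfg$voxel_size_um
  arr <- array(0, dim = shape_zyx)
  s <- cfg$spot_sigma_um
  r_vox <- ceiling(4 * s / vox)
  for (i in seq_len(nrow(centroids_um))) {
    c_um <- centroids_um[i, ]
    ci <- round(c_um / vox)
    zi <- max(0, ci[1] - r_vox[1]):min(shape_zyx[1] - 1, ci[1] + r_vox[1])
    yi <- max(0, ci[2] - r_vox[2]):min(shape_zyx[2] - 1, ci[2] + r_vox[2])
    xi <- max(0, ci[3] - r_vox[3]):min(shape_zyx[3] - 1, ci[3] + r_vox[3])
    if (!length(zi) || !length(yi) || !length(xi)) next
    # slice-integrated axial profile, normalised so a slice-centred spot
    # keeps peak `amplitude`
    zc <- zi * vox[1]
    gz <- stats::pnorm((zc + vox[1] / 2 - c_um[1]) / s) -
          stats::pnorm((zc - vox[1] / 2 - c_um[1]) / s)
    gz <- gz / (stats::pnorm(vox[1] / (2 * s)) - stats::pnorm(-vox[1] / (2 * s)))
    gy <- exp(-(yi * vox[2] - c_um[2])^2 / (2 * s^2))
    gx <- exp(-(xi * vox[3] - c_um[3])^2 / (2 * s^2))
    g <- outer(gz, outer(gy, gx)) * cfg$amplitude
    arr[zi + 1, yi + 1, xi + 1] <-
      arr[zi + 1, yi + 1, xi + 1, drop = FALSE] + g
  }
  arr <- arr + cfg$background_level
  if (cfg$noise_sd > 0)
    arr <- arr + stats::rnorm(length(arr), 0, cfg$noise_sd)
  arr[arr < 0] <- 0
  dim(arr) <- c(1, shape_zyx)
  image_stack(arr, vox, channel)
}

#' Sample a two-marker lineage census mosaic
#'
#' Places `n_cells_per_region` reference-marker-positive cells uniformly
#' inside each requested atlas region; each cell is independently
#' double-positive (lineage reporter) with that region's
#' `p_double_positive`. Uses the current RNG state.
#'
#' @param cfg a [synth_config()].
#' @param atlas a [region_atlas()].
#' @param regions region names to populate; default all present.
#' @return data.frame: `cell_id`, `region_label`, `y_um`, `x_um`,
#'   `double_positive`.
#' @export
sample_census <- function(cfg, atlas, regions = atlas_regions(atlas)) {
  if (length(regions) == 0) stop("no regions requested")
  n_per <- cfg$n_cells_per_region
  if (length(n_per) == 1) n_per <- stats::setNames(rep(n_per,
    length(regions)), regions)
  out <- list()
  next_id <- 1L
  for (rg in regions) {
    code <- atlas$label_map[[rg]]
    idx <- which(atlas$labels == code, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("region has zero area: ", rg)
    n <- n_per[[rg]]
    if (n < 1) stop("n_cells must be >= 1 for region ", rg)
    pick <- sample.int(nrow(idx), n, replace = TRUE)
    jit <- matrix(stats::runif(2 * n, -0.5, 0.5), n, 2)
    pos <- (idx[pick, , drop = FALSE] - 1 + jit) *
      rep(atlas$pixel_size_um, each = n)
    p <- cfg$p_double_positive[[rg]]
    if (is.null(p)) stop("no p_double_positive for region ", rg)
    out[[rg]] <- data.frame(
      cell_id = next_id:(next_id + n - 1L),
      region_label = rg,
      y_um = pos[, 1], x_um = pos[, 2],
      double_positive = stats::runif(n) < p)
    next_id <- next_id + n
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Synthetic nucleus grid
#'
#' A deterministic label image of disc nuclei on a regular grid — the
#' geometric substrate for puncta-per-nucleus and census recovery at scale
#' without rendering full images.
#'
#' @param n number of nuclei.
#' @param radius_um disc radius.
#' @param spacing_um centre-to-centre spacing (>= 2 * radius).
#' @param pixel_size_um `(y, x)` micrometres per pixel.
#' @return a `NucleusSet`: `centroids_um` (n x 2 `(y, x)`), `radii_um`,
#'   `labels` (integer matrix), `pixel_size_um`.
#' @export
synthetic_nucleus_grid <- function(n, radius_um = 3, spacing_um = 12,
                                   pixel_size_um = c(1, 1)) {
  stopifnot(spacing_um >= 2 * radius_um)
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  cy <- (seq_len(nrow_g) - 0.5) * spacing_um
  cx <- (seq_len(ncol_g) - 0.5) * spacing_um
  centers <- as.matrix(expand.grid(y_um = cy, x_um = cx))[seq_len(n), ,
                                                          drop = FALSE]
  ny <- ceiling(nrow_g * spacing_um / pixel_size_um[1])
  nx <- ceiling(ncol_g * spacing_um / pixel_size_um[2])
  labels <- matrix(0L, ny, nx)
  yy <- (seq_len(ny) - 1) * pixel_size_um[1]
  xx <- (seq_len(nx) - 1) * pixel_size_um[2]
  for (i in seq_len(n)) {
    yi <- which(abs(yy - centers[i, 1]) <= radius_um)
    xi <- which(abs(xx - centers[i, 2]) <= radius_um)
    sub <- outer((yy[yi] - centers[i, 1])^2, (xx[xi] - centers[i, 2])^2, `+`)
    labels[yi, xi][sub <= radius_um^2] <- i
  }
  structure(list(centroids_um = centers, radii_um = rep(radius_um, n),
                 labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "NucleusSet")
}

#' Simulate a complete synthetic septum field
#'
#' Orchestrates the generator: builds the atlas, places sparse astrocytes in
#' each region (MS cells use the configured orientation concentration, LS
#' cells are isotropic, mirroring the regional contrast under study),
#' renders the multichannel stack, samples a synaptic puncta field over the
#' whole stack box and a lineage census. Per-cell and per-assay draws use
#' counter-based substreams of `seed`.
#'
#' @param cfg a [synth_config()].
#' @param seed integer run seed (overrides `cfg$seed`).
#' @param shape_yx atlas/image shape in pixels.
#' @param n_astro_per_region sparse-labelled astrocytes rendered per region.
#' @return list: `atlas`, `cells` (GroundTruthCell list), `stack`,
#'   `puncta` (GroundTruthPuncta), `census` (data.frame), `seed`, `cfg`.
#' @export
simulate_septum <- function(cfg = synth_config(), seed = cfg$seed,
                            shape_yx = c(320, 320), n_astro_per_region = 1) {
  atlas <- make_atlas(shape_yx, pixel_size_um = cfg$voxel_size_um[2:3])
  fov_um <- (dim(atlas$labels) - 1) * atlas$pixel_size_um
  regions <- atlas_regions(atlas)
  margin <- cfg$branch_length_mean_um * 0.4
  cells <- list(); cid <- 1L
  for (ri in seq_along(regions)) {
    rg <- regions[ri]
    code <- atlas$label_map[[rg]]
    idx <- which(atlas$labels == code, arr.ind = TRUE)
    for (k in seq_len(n_astro_per_region)) {
      # prefer region pixels at least `margin` from the field border so
      # somata stay inside their region; clamp only as a last resort on
      # fields too small to hold the inset
      pos_um <- sweep(idx - 1, 2, atlas$pixel_size_um, `*`)
      inset <- pos_um[,1] >= margin & pos_um[,1] <= fov_um[1] - margin &
               pos_um[,2] >= margin & pos_um[,2] <= fov_um[2] - margin
      idx_ok <- idx[if (any(inset)) inset else rep(TRUE, nrow(idx)), ,
                    drop = FALSE]
      cell <- with_substream(seed, cid, {
        pos_px <- idx_ok[sample.int(nrow(idx_ok), 1), ]
        soma <- pmin(pmax((pos_px - 1) * atlas$pixel_size_um, margin),
                     fov_um - margin)
        kap <- if (rg == "MS") cfg$orientation_kappa else 0
        cfg_r <- cfg; cfg_r$orientation_kappa <- kap
        sample_arbor(cfg_r, soma, cell_id = cid)
      })
      cell$region_label <- rg
      cells[[cid]] <- cell
      cid <- cid + 1L
    }
  }
  # drop colliding somata (keep first of each close pair)
  somata <- do.call(rbind, lapply(cells, `[[`, "soma_yx_um"))
  keep <- rep(TRUE, length(cells))
  if (length(cells) > 1) {
    d <- as.matrix(stats::dist(somata))
    for (i in seq_along(cells)) for (j in seq_len(i - 1))
      if (keep[j] && d[i, j] < 2 * cfg$nucleus_radius_um) keep[i] <- FALSE
  }
  cells <- cells[keep]
  stack <- with_substream(seed, 10001L, render_cells(cells, cfg, atlas = atlas))
  box <- c(cfg$n_z * cfg$voxel_size_um[1], fov_um)
  puncta <- with_substream(seed, 10002L, sample_puncta(cfg, box))
  census <- with_substream(seed, 10003L, sample_census(cfg, atlas))
  list(atlas = atlas, cells = cells, stack = stack, puncta = puncta,
       census = census, seed = seed, cfg = cfg)
}

#' Write a simulation to disk
#'
#' Writes `stack.tif`, `atlas.tif` (each with a JSON sidecar),
#' `truth_cells.json`, `truth_puncta.json`, `truth_census.csv` and a
#' `manifest.json` (seed, config, package version).
#'
#' @param sim result of [simulate_septum()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(sim$stack, file.path(dir, "stack.tif"),
              scale = max(sim$stack$voxels))
  write_atlas(sim$atlas, file.path(dir, "atlas.tif"))
  cells_json <- lapply(sim$cells, function(cl) {
    cl$tips_um <- unname(apply(cl$tips_um, 1, as.numeric, simplify = FALSE))
    unclass(cl)
  })
  jsonlite::write_json(cells_json, file.path(dir, "truth_cells.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(unclass(sim$puncta), function(x)
    if (is.matrix(x)) unname(apply(x, 1, as.numeric, simplify = FALSE)) else x),
    file.path(dir, "truth_puncta.json"), auto_unbox = TRUE, digits = NA)
  write_table(sim$census, file.path(dir, "truth_census.csv"))
  jsonlite::write_json(list(seed = sim$seed, config = unclass(sim$cfg),
                            package = "septastro",
                            version = as.character(utils::packageVersion("septastro"))),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
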