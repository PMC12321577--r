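# Lineage census: marker positivity per nucleus, per-region lineage
# fractions, and regional astrocyte densities.

#' Classify cells by nuclear marker intensity
#'
#' Mean intensity inside each nuclear mask per marker channel; a cell is
#' positive when its mean exceeds background mean + k * background s.d.
#' (k = `cfg$marker_threshold_k`), the background being estimated from
#' pixels outside all dilated nuclear masks. A background-referenced
#' threshold stays well defined when a region is ~0% or ~100% positive,
#' where bimodality-based thresholds fail.
#'
#' @param stack an [image_stack()].
#' @param nuclei a `NucleusSet`.
#' @param markers character vector of marker channel names.
#' @param cfg a [septastro_config()].
#' @param atlas optional [region_atlas()]; when given, each cell is
#'   assigned the region of its nucleus centroid (`"outside"` if
#'   background).
#' @return a `CellCensus` data.frame: `cell_id`, `region_label`, and per
#'   marker `<m>_mean` and `<m>_pos`.
#' @export
classify_cells <- function(stack, nuclei, markers, cfg = septastro_config(),
                           atlas = NULL) {
  missing_ch <- setdiff(markers, stack$channel_names)
  if (length(missing_ch) > 0)
    stop("marker channel(s) not in stack: ", paste(missing_ch, collapse = ", "))
  n <- nrow(nuclei$centroids_um)
  lab <- nuclei$labels
  dil <- as.matrix(EBImage::dilate(lab > 0, EBImage::makeBrush(5, "disc"))) > 0
  bg_idx <- which(!dil)
  if (length(bg_idx) == 0) stop("no background pixels available")
  out <- data.frame(cell_id = seq_len(n))
  out$region_label <- if (is.null(atlas)) NA_character_ else {
    vapply(seq_len(n), function(i) {
      cpx <- pmin(pmax(round(nuclei$centroids_um[i, ] /
                               atlas$pixel_size_um) + 1, 1),
                  dim(atlas$labels))
      code <- atlas$labels[cpx[1], cpx[2]]
      if (code == 0) "outside" else
        names(atlas$label_map)[match(code, atlas$label_map)]
    }, character(1))
  }
  for (m in markers) {
    proj <- max_project(stack, m)
    bg <- proj[bg_idx]
    thr <- mean(bg) + cfg$marker_threshold_k * stats::sd(bg)
    means <- vapply(seq_len(n), function(i) {
      v <- proj[lab == i]
      if (length(v) == 0) 0 else mean(v)
    }, numeric(1))
    out[[paste0(m, "_mean")]] <- means
    out[[paste0(m, "_pos")]] <- means > thr
  }
  class(out) <- c("CellCensus", "data.frame")
  out
}

#' Build a CellCensus from a ground-truth table
#'
#' Wraps a simulated census ([sample_census()]) in the container the
#' fraction and density operators consume: the reference marker is positive
#' for every cell, the lineage marker follows `double_positive`.
#'
#' @param truth data.frame from [sample_census()].
#' @param ref_marker,lineage_marker marker names for the columns.
#' @return a `CellCensus` data.frame.
#' @export
census_from_truth <- function(truth, ref_marker = "Sox9",
                              lineage_marker = "GFP") {
  out <- data.frame(cell_id = truth$cell_id,
                    region_label = truth$region_label)
  out[[paste0(ref_marker, "_pos")]] <- TRUE
  out[[paste0(lineage_marker, "_pos")]] <- as.logical(truth$double_positive)
  class(out) <- c("CellCensus", "data.frame")
  out
}

#' Per-region lineage fractions
#'
#' For each region: `n_ref` reference-marker-positive cells (e.g. Sox9+
#' astrocytes), `n_lineage` lineage-reporter-positive cells, `n_double`
#' double positives, the fraction of the astrocyte population carrying the
#' lineage label (`fraction_of_ref = n_double / n_ref`) and the fraction of
#' the lineage made of astrocytes (`fraction_of_lineage`). A region with a
#' zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param census a `CellCensus`.
#' @param atlas a [region_atlas()] (regions to report).
#' @param ref_marker,lineage_marker marker names.
#' @return a `LineageFractions` data.frame, one row per region.
#' @export
lineage_fractions <- function(census, atlas, ref_marker = "Sox9",
                              lineage_marker = "GFP") {
  regions <- atlas_regions(atlas)
  ref_col <- paste0(ref_marker, "_pos")
  lin_col <- paste0(lineage_marker, "_pos")
  if (!all(c(ref_col, lin_col) %in% names(census)))
    stop("census lacks marker columns ", ref_col, " / ", lin_col)
  out <- do.call(rbind, lapply(regions, function(rg) {
    sub <- census[census$region_label == rg, , drop = FALSE]
    n_ref <- sum(sub[[ref_col]])
    n_lin <- sum(sub[[lin_col]])
    n_dbl <- sum(sub[[ref_col]] & sub[[lin_col]])
    data.frame(region_label = rg, n_ref = n_ref, n_lineage = n_lin,
               n_double = n_dbl,
               fraction_of_ref = if (n_ref > 0) n_dbl / n_ref else NA_real_,
               fraction_of_lineage = if (n_lin > 0) n_dbl / n_lin else NA_real_)
  }))
  class(out) <- c("LineageFractions", "data.frame")
  out
}

#' Regional astrocyte density
#'
#' Count of reference-marker-positive cells per region divided by the
#' region area, in cells per square millimetre.
#'
#' @param census a `CellCensus`.
#' @param atlas a [region_atlas()].
#' @param ref_marker marker defining the counted population.
#' @return data.frame: `region_label`, `n_cells`, `area_mm2`,
#'   `density_per_mm2`.
#' @export
regional_cell_density <- function(census, atlas, ref_marker = "Sox9") {
  regions <- atlas_regions(atlas)
  ref_col <- paste0(ref_marker, "_pos")
  do.call(rbind, lapply(regions, function(rg) {
    area_mm2 <- region_area_um2(atlas, rg) * 1e-6
    if (area_mm2 <= 0) stop("zero-area region: ", rg)
    sub <- census[census$region_label == rg, , drop = FALSE]
    n <- sum(sub[[ref_col]])
    data.frame(region_label = rg, n_cells = n, area_mm2 = area_mm2,
               density_per_mm2 = n / area_mm2)
  }))
}
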