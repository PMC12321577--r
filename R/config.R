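#' Analysis configuration
#'
#' All tunable parameters of the measurement pipeline, with units and
#' defaults. Unknown keys are rejected outright so a typo in a config file
#' can never silently fall back to a default.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details Parameters (units in the name or noted):
#' \describe{
#'   \item{voxel_size_um}{numeric (z, y, x), micrometres per voxel used when
#'     generating synthetic stacks. Default `c(1.0, 0.2, 0.2)`, typical
#'     confocal sampling at x100 for a 5 um stack.}
#'   \item{stack_depth_um}{depth used to convert 2-D territory areas to
#'     volumes. Default 5.}
#'   \item{nucleus_radius_um}{nominal nuclear radius for detection and
#'     rendering. Default 3.}
#'   \item{nucleus_min_response}{minimum blob response (scale-normalised
#'     Laplacian-of-Gaussian) for a nucleus detection; `NULL` picks a robust
#'     data-driven floor.}
#'   \item{cell_isolation_radius_um}{sparse-labelling assumption: at most one
#'     labelled cell within this radius of a nucleus. Default 40.}
#'   \item{arbor_window_um}{half-width of the window around a nucleus used
#'     for local Otsu thresholding of the reporter channel. Default 60.}
#'   \item{arbor_threshold}{fixed intensity threshold overriding Otsu when
#'     set (useful on noise-free images, where Otsu is degenerate).}
#'   \item{min_spur_um}{skeleton spurs shorter than this are pruned.
#'     Default 2 (one nucleus radius).}
#'   \item{orientation_min_elongation}{cells with length-to-width ratio below
#'     this have undefined orientation. Default 1.1.}
#'   \item{angle_bin_edges_deg}{bin edges for orientation fractions.
#'     Default `c(0, 30, 60, 90)`.}
#'   \item{spot_sigma_um}{expected puncta Gaussian sigma. Default 0.15
#'     (sub-resolution synaptic markers).}
#'   \item{spot_min_response}{minimum LoG response for a punctum; `NULL`
#'     picks a robust floor from the response image.}
#'   \item{min_spot_separation_um}{detections closer than this are merged,
#'     keeping the stronger. Default 0.3.}
#'   \item{coloc_max_dist_um}{maximum centroid distance for a pre/post pair
#'     to count as one synapse. Default 0.5, about one optical PSF.}
#'   \item{marker_threshold_k}{positivity threshold = background mean +
#'     k * background s.d. Default 3.}
#'   \item{nucleus_margin_um}{dilation margin when assigning puncta to
#'     nuclei. Default 0.}
#' }
#'
#' @return a named list of class `"septastro_config"`.
#' @export
#' @examples
#' cfg <- septastro_config(min_spur_um = 3)
#' cfg$min_spur_um
septastro_config <- function(...) {
  defaults <- list(
    voxel_size_um            = c(1.0, 0.2, 0.2),
    stack_depth_um           = 5,
    nucleus_radius_um        = 3,
    nucleus_min_response     = NULL,
    cell_isolation_radius_um = 40,
    arbor_window_um          = 60,
    arbor_threshold          = NULL,
    min_spur_um              = 2,
    orientation_min_elongation = 1.1,
    angle_bin_edges_deg      = c(0, 30, 60, 90),
    spot_sigma_um            = 0.15,
    spot_min_response        = NULL,
    min_spot_separation_um   = 0.3,
    coloc_max_dist_um        = 0.5,
    marker_threshold_k       = 3,
    nucleus_margin_um        = 0
  )
  cfg <- utils::modifyList(defaults, validate_keys(list(...), names(defaults),
                                                   "septastro_config"))
  validate_config(cfg)
  structure(cfg, class = "septastro_config")
}

#' Synthetic-data configuration
#'
#' Parameters of the ground-truth simulator. Defaults describe a
#' medial-septum-like field: star-shaped astrocyte arbors with
#' midline-concentrated branch orientations, sub-resolution synaptic puncta
#' with a partially colocalized pre/post pair structure, Poisson RNAscope
#' counts per nucleus, and a two-marker lineage mosaic whose per-region
#' double-positive probabilities follow the regional pattern measured in
#' septal tissue (high in MS, near zero dorsally in LS).
#'
#' @param ... named overrides; unknown names are an error.
#' @return named list of class `"synth_config"`.
#' @export
synth_config <- function(...) {
  defaults <- list(
    seed                   = 1L,
    # arbor geometry
    n_branches             = 6L,
    branch_length_mean_um  = 40,
    branch_length_sd_um    = 8,
    branch_width_um        = 1.0,
    orientation_kappa      = 8,
    orientation_mu_deg     = 0,
    nucleus_radius_um      = 3,
    # rendering
    psf_sigma_um           = 0.5,
    background_level       = 10,
    noise_sd               = 2,
    amplitude              = 100,
    voxel_size_um          = c(1.0, 0.2, 0.2),
    n_z                    = 5L,
    # puncta
    lambda_pre_per_um3     = 0.02,
    lambda_post_per_um3    = 0.02,
    coloc_fraction         = 0.3,
    coloc_radius_um        = 0.3,
    spot_sigma_um          = 0.15,
    # census
    n_cells_per_region     = 100L,
    p_double_positive      = c(MS = 0.74, dLS = 0.001, iLS = 0.02, vLS = 0.12),
    # rnascope
    poisson_mean_per_nucleus = c(MS = 8, dLS = 8, iLS = 8, vLS = 8)
  )
  cfg <- utils::modifyList(defaults, validate_keys(list(...), names(defaults),
                                                   "synth_config"))
  stopifnot(cfg$n_branches >= 2, cfg$branch_length_mean_um > 0,
            cfg$orientation_kappa >= 0, cfg$coloc_fraction >= 0,
            cfg$coloc_fraction <= 1, cfg$lambda_pre_per_um3 >= 0,
            cfg$lambda_post_per_um3 >= 0,
            all(cfg$p_double_positive >= 0 & cfg$p_double_positive <= 1),
            all(cfg$poisson_mean_per_nucleus >= 0))
  if (cfg$coloc_fraction > 0 && cfg$coloc_radius_um <= 0)
    stop("coloc_radius_um must be > 0 when coloc_fraction > 0")
  structure(cfg, class = "synth_config")
}

validate_keys <- function(overrides, allowed, what) {
  if (length(overrides) == 0) return(overrides)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop(what, ": all overrides must be named")
  bad <- setdiff(nm, allowed)
  if (length(bad) > 0)
    stop(what, ": unknown key(s): ", paste(bad, collapse = ", "))
  overrides
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$voxel_size_um) == 3, all(cfg$voxel_size_um > 0),
            cfg$stack_depth_um > 0, cfg$nucleus_radius_um > 0,
            cfg$min_spur_um >= 0, cfg$orientation_min_elongation >= 1,
            cfg$spot_sigma_um > 0, cfg$min_spot_separation_um >= 0,
            cfg$coloc_max_dist_um > 0, cfg$marker_threshold_k > 0,
            cfg$nucleus_margin_um >= 0)
  edges <- cfg$angle_bin_edges_deg
  if (length(edges) < 2 || any(diff(edges) <= 0) ||
      edges[1] != 0 || edges[length(edges)] != 90)
    stop("angle_bin_edges_deg must be strictly increasing and span [0, 90]")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Reads a YAML file of overrides and applies it to [septastro_config()]
#' (section `pipeline`) and [synth_config()] (section `synth`). Unknown keys
#' anywhere are a hard error.
#'
#' @param path YAML file.
#' @return list with elements `pipeline` and `synth`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("pipeline", "synth"))
  if (length(bad) > 0)
    stop("unknown top-level config section(s): ", paste(bad, collapse = ", "))
  list(
    pipeline = do.call(septastro_config, as.list(raw$pipeline)),
    synth    = do.call(synth_config, as.list(raw$synth))
  )
}
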