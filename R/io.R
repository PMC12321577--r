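#' Multichannel image stack
#'
#' Container for a multichannel fluorescence z-stack: a numeric array indexed
#' `(channel, z, y, x)` plus physical voxel size and channel names.
#' Coordinates are 0-based voxel indices; physical positions in micrometres
#' are `index * voxel_size_um`, with voxel centres at integer indices.
#'
#' @param voxels numeric array `(channel, z, y, x)`; finite, non-negative.
#' @param voxel_size_um numeric `(z, y, x)` micrometres per voxel, all > 0.
#' @param channel_names character, one unique label per channel.
#' @return object of class `"ImageStack"`.
#' @export
image_stack <- function(voxels, voxel_size_um, channel_names) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be 3 positive values (z, y, x)")
  if (length(channel_names) != dim(voxels)[1])
    stop("channel_names length (", length(channel_names),
         ") must equal channel count (", dim(voxels)[1], ")")
  if (anyDuplicated(channel_names))
    stop("channel_names must be unique")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and >= 0")
  structure(list(voxels = voxels,
                 voxel_size_um = as.numeric(voxel_size_um),
                 channel_names = as.character(channel_names)),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ImageStack: %d channel(s) [%s], z=%d, y=%d, x=%d; voxel %s um\n",
              d[1], paste(x$channel_names, collapse = ", "), d[2], d[3], d[4],
              paste(signif(x$voxel_size_um, 3), collapse = " x ")))
  invisible(x)
}

#' Extract one channel as a (z, y, x) array
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  i <- match(channel, stack$channel_names)
  if (is.na(i)) stop("channel not found: ", channel, " (have: ",
                     paste(stack$channel_names, collapse = ", "), ")")
  arr <- stack$voxels[i, , , , drop = FALSE]
  dim(arr) <- dim(stack$voxels)[2:4]
  arr
}

#' Maximum-intensity projection of a channel
#' @inheritParams get_channel
#' @return numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel) {
  arr <- get_channel(stack, channel)
  apply(arr, c(2, 3), max)
}

#' Septal region atlas
#'
#' A 2-D coronal label image over the septum plus the midline axis against
#' which astrocyte orientation is measured. Labels: 0 background, 1 MS,
#' 2 dLS, 3 iLS, 4 vLS.
#'
#' @param labels integer matrix `(y, x)`.
#' @param midline_axis numeric `(y, x)` direction; normalised to unit length.
#' @param pixel_size_um numeric `(y, x)` micrometres per pixel.
#' @return object of class `"RegionAtlas"` with fields `labels`,
#'   `label_map` (named integer vector), `midline_axis`, `pixel_size_um`.
#' @export
region_atlas <- function(labels, midline_axis = c(1, 0),
                         pixel_size_um = c(0.2, 0.2)) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  label_map <- c(background = 0L, MS = 1L, dLS = 2L, iLS = 3L, vLS = 4L)
  bad <- setdiff(unique(as.vector(labels)), unname(label_map))
  if (length(bad) > 0)
    stop("atlas labels outside {0..4}: ", paste(sort(bad), collapse = ", "))
  n <- sqrt(sum(midline_axis^2))
  if (!is.finite(n) || n == 0) stop("midline_axis must be nonzero")
  stopifnot(length(pixel_size_um) == 2, all(pixel_size_um > 0))
  structure(list(labels = labels, label_map = label_map,
                 midline_axis = as.numeric(midline_axis) / n,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "RegionAtlas")
}

#' Region names present in an atlas (excluding background)
#' @param atlas a [region_atlas()].
#' @return character vector.
#' @export
atlas_regions <- function(atlas) {
  present <- intersect(unname(atlas$label_map), unique(as.vector(atlas$labels)))
  names(atlas$label_map)[atlas$label_map %in% setdiff(present, 0L)]
}

#' Area of one atlas region in square micrometres
#' @param atlas a [region_atlas()].
#' @param region region name ("MS", "dLS", "iLS", "vLS").
#' @return numeric scalar (um^2).
#' @export
region_area_um2 <- function(atlas, region) {
  code <- atlas$label_map[[region]]
  if (is.null(code)) stop("unknown region: ", region)
  sum(atlas$labels == code) * prod(atlas$pixel_size_um)
}

# ---- stack I/O ------------------------------------------------------------

#' Write an ImageStack to TIFF
#'
#' Pages are stored channel-major (all z of channel 1, then channel 2, ...).
#' Because baseline TIFF tags cannot carry the voxel size or channel names,
#' a JSON sidecar `<path>.json` records them; [read_stack()] reads it back.
#' Intensities are stored as 32-bit floats, scaled by `scale`.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param scale divide intensities by this before writing (writeTIFF expects
#'   values in `[0, 1]`); recorded in the sidecar and undone on read.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = NULL) {
  d <- dim(stack$voxels)
  mx <- max(stack$voxels)
  if (is.null(scale)) scale <- if (mx > 1) mx else 1
  pages <- vector("list", d[1] * d[2])
  k <- 1
  for (ci in seq_len(d[1])) for (zi in seq_len(d[2])) {
    pg <- stack$voxels[ci, zi, , ] / scale
    # the 32-bit codec stores trunc(v * (2^32-1)) but reads back u / 2^32;
    # pre-adjust so the stored integer is round(v * 2^32) and values on the
    # k/2^32 grid (any dyadic rational below 1) round-trip exactly
    u <- pmin(round(pmin(pmax(pg, 0), 1) * 2^32), 2^32 - 1)
    pages[[k]] <- pmin((u + 0.5) / (2^32 - 1), 1)
    k <- k + 1
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(voxel_size_um = stack$voxel_size_um,
               channel_names = stack$channel_names,
               n_channels = d[1], n_z = d[2], scale = scale,
               page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TIFF / OME-TIFF z-stack
#'
#' Reads the pages of a multichannel z-stack into an [image_stack()]. The
#' voxel size and channel layout come from, in order of preference: the JSON
#' sidecar written by [write_stack()]; OME-XML `PhysicalSize*` metadata in
#' the TIFF description (OME-TIFF); the explicit `voxel_size_override`.
#' With none of these, reading fails naming the missing field.
#'
#' @param path TIFF file.
#' @param voxel_size_override optional `(z, y, x)` micrometres.
#' @param channel_names optional names when no sidecar is present; default
#'   `ch1..chN` (single-channel assumed unless metadata says otherwise).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_override = NULL, channel_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    ome <- parse_ome_description(attr(pages[[1]], "description"))
    if (!is.null(ome)) meta <- ome
  }
  n_pages <- length(pages)
  if (!is.null(meta)) {
    vz <- as.numeric(meta$voxel_size_um)
    nc <- as.integer(meta$n_channels %||% 1L)
    nz <- as.integer(meta$n_z %||% (n_pages / nc))
    ch <- as.character(meta$channel_names %||% paste0("ch", seq_len(nc)))
    scl <- as.numeric(meta$scale %||% 1)
  } else {
    if (is.null(voxel_size_override))
      stop("no voxel size available for ", path,
           ": missing sidecar/OME metadata field 'voxel_size_um'; ",
           "supply voxel_size_override")
    vz <- as.numeric(voxel_size_override)
    nc <- if (is.null(channel_names)) 1L else length(channel_names)
    nz <- n_pages / nc
    ch <- channel_names %||% paste0("ch", seq_len(nc))
    scl <- 1
  }
  if (nc * nz != n_pages)
    stop("page count ", n_pages, " inconsistent with ", nc, " channels x ",
         nz, " z-planes")
  p1 <- pages[[1]]
  if (length(dim(p1)) == 3) p1 <- p1[, , 1]   # drop grey+alpha style planes
  vox <- array(0, dim = c(nc, nz, nrow(p1), ncol(p1)))
  k <- 1
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    pg <- pages[[k]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    vox[ci, zi, , ] <- pg * scl
    k <- k + 1
  }
  image_stack(vox, vz, ch)
}

# OME-XML PhysicalSizeX/Y/Z (micrometre units assumed, the OME default here)
parse_ome_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE))
    return(NULL)
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  px <- xml2::xml_find_first(doc, "//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(NULL)
  getn <- function(a) suppressWarnings(as.numeric(xml2::xml_attr(px, a)))
  sz <- c(getn("PhysicalSizeZ"), getn("PhysicalSizeY"), getn("PhysicalSizeX"))
  if (any(is.na(sz)))
    stop("OME metadata present but missing PhysicalSize",
         c("Z", "Y", "X")[which(is.na(sz))[1]])
  nc <- getn("SizeC"); nz <- getn("SizeZ")
  list(voxel_size_um = sz,
       n_channels = if (is.na(nc)) 1L else as.integer(nc),
       n_z = if (is.na(nz)) NULL else as.integer(nz),
       channel_names = NULL, scale = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- atlas I/O ------------------------------------------------------------

#' Write a RegionAtlas label image
#'
#' Labels go to a TIFF (values scaled into `[0,1]` by 1/255) with a JSON
#' sidecar carrying the midline axis and pixel size.
#' @param atlas a [region_atlas()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  tiff::writeTIFF(atlas$labels / 255, path, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(midline_axis = atlas$midline_axis,
                            pixel_size_um = atlas$pixel_size_um),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a region-atlas label image
#'
#' @param path TIFF label image (integer labels 0..4, possibly scaled by
#'   1/255 as written by [write_atlas()]).
#' @param midline_axis `(y, x)` direction of the septal midline; normalised.
#'   Defaults to the sidecar value when one exists.
#' @param pixel_size_um `(y, x)` micrometres per pixel; sidecar default.
#' @return a [region_atlas()]; labels outside 0..4 are a validation error.
#' @export
read_atlas <- function(path, midline_axis = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  labels <- round(img * 255)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    midline_axis <- midline_axis %||% meta$midline_axis
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
  }
  if (is.null(midline_axis)) stop("midline_axis required (no sidecar)")
  region_atlas(labels, midline_axis, pixel_size_um %||% c(0.2, 0.2))
}

# ---- tables ---------------------------------------------------------------

#' Write a table of flat records to CSV
#'
#' @param records data.frame, or list of same-named lists. All records must
#'   share one field set.
#' @param path output CSV.
#' @param schema character vector of column names, required when `records`
#'   is empty (header-only CSV).
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema = NULL) {
  if (is.data.frame(records)) {
    df <- records
  } else if (is.list(records)) {
    if (length(records) == 0) {
      if (is.null(schema)) stop("empty record set requires a schema")
      df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(schema)),
                                          schema))
    } else {
      fields <- lapply(records, names)
      if (any(vapply(fields, function(f)
        !identical(sort(f), sort(fields[[1]])), logical(1))))
        stop("records have heterogeneous field sets")
      df <- do.call(rbind, lapply(records, function(r)
        as.data.frame(r[fields[[1]]], stringsAsFactors = FALSE)))
    }
  } else stop("records must be a data.frame or list of records")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path CSV file.
#' @return data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}
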