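#' Marker panel
#'
#' A panel maps TIFF page/channel order to marker names and carries the
#' physical pixel size. Channels are numbered contiguously from 0 in file
#' order (the convention of multipage OME-TIFF exports); within R, channel
#' `i` of the panel is plane `i + 1` of the image array.
#'
#' @param markers character vector of unique marker names, in channel order.
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @return a tibble with columns `channel` (0-based integer) and `marker`,
#'   with attribute `pixel_size_um`.
#' @export
marker_panel <- function(markers, pixel_size_um = 1) {
  if (anyDuplicated(markers)) stop_validation("marker names must be unique")
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  out <- tibble(channel = seq_along(markers) - 1L, marker = as.character(markers))
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

#' Multiplex image container
#'
#' Bundles a channel stack with its panel. `channels` is a 3D numeric array
#' indexed `[channel, row, col]`; intensities are non-negative floats in the
#' instrument's arbitrary units (no rescaling on read).
#'
#' @param channels 3D array (channel x row x col) of finite values >= 0, or a
#'   list of equal-sized matrices.
#' @param panel a [marker_panel()] whose length equals the channel count.
#' @param sample_id,core_id identifiers carried into downstream tables.
#' @return an object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, panel, sample_id = "s1", core_id = "c1") {
  if (is.list(channels)) {
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1) stop_format("all channel matrices must share a size")
    channels <- aperm(simplify2array(channels), c(3, 1, 2))
  }
  if (length(dim(channels)) != 3L) stop_format("`channels` must be a 3D array")
  if (dim(channels)[1] != nrow(panel))
    stop_format(sprintf("channel count (%d) does not match panel length (%d)",
                        dim(channels)[1], nrow(panel)))
  if (!all(is.finite(channels)) || any(channels < 0))
    stop_validation("intensities must be finite and >= 0")
  structure(
    list(channels = channels, panel = panel,
         pixel_size_um = attr(panel, "pixel_size_um") %||% 1,
         sample_id = sample_id, core_id = core_id),
    class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<multiplex_image> %s/%s: %d channels, %d x %d px @ %.3g um/px\n",
              x$sample_id, x$core_id, d[1], d[2], d[3], x$pixel_size_um))
  cat(" markers:", paste(x$panel$marker, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one marker channel as a matrix
#' @param image a [multiplex_image()].
#' @param marker marker name present in the panel.
#' @return numeric matrix (row x col).
#' @export
get_channel <- function(image, marker) {
  idx <- match(marker, image$panel$marker)
  if (is.na(idx)) stop_panel(sprintf("marker '%s' not in panel (%s)", marker,
                                     paste(image$panel$marker, collapse = ", ")))
  image$channels[idx, , ]
}

#' Write / read a multiplex image as multipage TIFF
#'
#' Channels are stored as 32-bit float pages in panel order. TIFF float pages
#' hold values in \[0,1\], so intensities are divided by a per-file scale
#' (the global max) recorded in a `<path>.json` sidecar and restored on read;
#' the round trip is the identity at float32 precision.
#'
#' @param image a [multiplex_image()].
#' @param path output `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_multiplex_image <- function(image, path) {
  d <- dim(image$channels)
  scale <- max(image$channels, 1e-12)
  pages <- lapply(seq_len(d[1]), function(i) image$channels[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(scale = scale, sample_id = image$sample_id, core_id = image$core_id,
         pixel_size_um = image$pixel_size_um, markers = image$panel$marker),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_multiplex_image
#' @param panel a [marker_panel()]; page count must equal panel length.
#' @param sample_id,core_id identifiers; defaults taken from the sidecar when
#'   present.
#' @export
read_multiplex_image <- function(path, panel, sample_id = NULL, core_id = NULL) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != nrow(panel))
    stop_format(sprintf("TIFF has %d pages but panel has %d entries",
                        length(pages), nrow(panel)))
  scale <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    scale <- meta$scale %||% 1
    sample_id <- sample_id %||% meta$sample_id
    core_id <- core_id %||% meta$core_id
  }
  arr <- aperm(simplify2array(lapply(pages, function(p) p * scale)), c(3, 1, 2))
  multiplex_image(arr, panel, sample_id %||% "s1", core_id %||% "c1")
}

#' Write / read 16-bit label masks
#'
#' Label masks are non-negative integer rasters, 0 = background; labels need
#' not be contiguous. Stored as single-page 16-bit TIFF.
#'
#' @param mask integer matrix of labels in \[0, 65535\].
#' @param path `.tiff` path.
#' @export
write_label_mask <- function(mask, path) {
  if (any(mask < 0) || any(mask != round(mask)))
    stop_validation("label mask must contain non-negative integers")
  if (max(mask) > 65535) stop_validation("labels exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @return `read_label_mask()` returns an integer matrix.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) stop_format("label mask must be a single-page TIFF")
  storage.mode(m) <- "integer"
  m
}

#' Read a per-cell CSV table
#'
#' Required columns: `cell_id`, `sample_id`, `core_id`, `row`, `col`; any
#' additional columns (marker means, shape features, labels) pass through
#' with row order preserved.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_cell_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("cell_id", "sample_id", "core_id", "row", "col"),
                "cell table")
  df
}

#' Read a clinical outcomes CSV
#'
#' Columns `sample_id`, `os_time` (months from diagnosis), `event`
#' (1 = death from any cause, 0 = censored); extra covariate columns pass
#' through. Sample ids must be unique and times finite and non-negative.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_clinical <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("sample_id", "os_time", "event"), "clinical table")
  validate_clinical(df)
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicated sample_id in clinical table")
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop_validation("os_time must be finite and >= 0")
  if (!all(df$event %in% c(0, 1)))
    stop_validation("event must be 0 or 1")
  as_tibble(df)
}

#' Read / write a run configuration
#'
#' Configurations are YAML with a `schema_version` field; every threshold and
#' seed used by [run_pipeline()] lives here rather than in code.
#'
#' @param path YAML path.
#' @return a named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop_schema("config lacks `schema_version`")
  cfg
}

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  if (is.null(config$schema_version)) config$schema_version <- 1L
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Summarize a label mask
#' @param mask integer label matrix.
#' @return tibble with `label` and `n_pixels` for each nonzero label.
#' @export
label_mask_summary <- function(mask) {
  tab <- table(mask[mask > 0])
  tibble(label = as.integer(names(tab)), n_pixels = as.integer(tab))
}
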