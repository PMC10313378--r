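stroma_classes <- c("none", "FRC", "LEC", "BEC")

new_stroma_map <- function(class_raster, thresholds, pixel_size_um) {
  structure(list(class_raster = class_raster, thresholds_used = thresholds,
                 pixel_size_um = pixel_size_um),
            class = "stroma_map")
}

#' @export
print.stroma_map <- function(x, ...) {
  tab <- tabulate(x$class_raster + 1L, 4L)
  cat(sprintf("<stroma_map> %d x %d px: FRC %.1f%%, LEC %.1f%%, BEC %.1f%%\n",
              nrow(x$class_raster), ncol(x$class_raster),
              100 * tab[2] / sum(tab), 100 * tab[3] / sum(tab),
              100 * tab[4] / sum(tab)))
  invisible(x)
}

#' Classify pixels into stromal compartments
#'
#' Implements the PDPN/CD31 gating of lymph-node stroma: after optional
#' Gaussian smoothing each channel is thresholded (Otsu by default, or fixed
#' values), and every pixel is assigned by the double gate
#' PDPN+CD31- = FRC, PDPN+CD31+ = LEC, PDPN-CD31+ = BEC, else none.
#' Pixels exactly at a threshold count as positive.
#'
#' @param image a [multiplex_image()] whose panel contains PDPN and CD31.
#' @param method `"otsu"` (per-channel Otsu threshold) or `"fixed"`.
#' @param fixed_thresholds named list/vector with `PDPN` and `CD31` values,
#'   required when `method = "fixed"`.
#' @param smooth_sigma Gaussian smoothing sd in pixels before thresholding
#'   (0 disables). The default 0.5 gives an effective one-pixel kernel:
#'   larger kernels are comparable to the fibre width itself and bleed
#'   signal across fibre borders, costing precision on thin structures.
#' @return a `stroma_map`: `class_raster` (integer matrix, 0 none / 1 FRC /
#'   2 LEC / 3 BEC), `thresholds_used`, `pixel_size_um`.
#' @export
classify_stroma_pixels <- function(image, method = c("otsu", "fixed"),
                                   fixed_thresholds = NULL, smooth_sigma = 0.5) {
  method <- match.arg(method)
  for (mk in c("PDPN", "CD31"))
    if (!mk %in% image$panel$marker)
      stop_panel(sprintf("panel lacks required marker '%s'", mk))
  chans <- lapply(c(PDPN = "PDPN", CD31 = "CD31"), function(mk) {
    x <- get_channel(image, mk)
    if (smooth_sigma > 0)
      x <- EBImage::imageData(EBImage::gblur(x, sigma = smooth_sigma))
    x
  })
  thr <- if (method == "otsu") {
    lapply(chans, otsu_threshold)
  } else {
    if (is.null(fixed_thresholds) ||
        !all(c("PDPN", "CD31") %in% names(fixed_thresholds)))
      stop_param("method='fixed' requires fixed_thresholds for PDPN and CD31")
    lapply(fixed_thresholds[c("PDPN", "CD31")], identity)
  }
  pdpn <- chans$PDPN >= thr$PDPN
  cd31 <- chans$CD31 >= thr$CD31
  cls <- matrix(0L, nrow(pdpn), ncol(pdpn))
  cls[pdpn & !cd31] <- 1L
  cls[pdpn & cd31] <- 2L
  cls[!pdpn & cd31] <- 3L
  new_stroma_map(cls, thresholds = thr, pixel_size_um = image$pixel_size_um)
}

#' Area occupied by each stromal compartment
#'
#' @param map a `stroma_map`.
#' @param denominator `"field"` (whole image) or `"tissue_mask"`.
#' @param tissue_mask logical/0-1 matrix when `denominator = "tissue_mask"`.
#' @return tibble with `class`, `n_pixels`, `fraction`, `area_mm2`. Over the
#'   field the four fractions sum to 1.
#' @export
area_occupied <- function(map, denominator = c("field", "tissue_mask"),
                          tissue_mask = NULL) {
  denominator <- match.arg(denominator)
  cls <- map$class_raster
  if (denominator == "tissue_mask") {
    if (is.null(tissue_mask) || !any(tissue_mask != 0))
      stop_degenerate("tissue mask is empty")
    keep <- tissue_mask != 0
    denom <- sum(keep)
    counts <- tabulate(cls[keep] + 1L, 4L)
  } else {
    denom <- length(cls)
    counts <- tabulate(cls + 1L, 4L)
  }
  tibble(class = stroma_classes, n_pixels = counts,
         fraction = counts / denom,
         area_mm2 = counts * (map$pixel_size_um / 1000)^2)
}

frc_pixels <- function(map) {
  idx <- which(map$class_raster == 1L)
  if (!length(idx))
    stop_degenerate("stroma map contains no FRC pixels")
  idx
}

#' Marker intensity over FRC pixels
#'
#' Mean and median pixel intensity of a marker restricted to FRC-class
#' pixels (e.g. PDPN level on FRCs, or FRC-associated PD-L1/PD-L2).
#'
#' @param image a [multiplex_image()].
#' @param map the matching `stroma_map`.
#' @param marker marker name.
#' @return tibble with `marker`, `mean_intensity`, `median_intensity`,
#'   `n_pixels`. Zero FRC pixels is an error, not a silent 0.
#' @export
frc_marker_intensity <- function(image, map, marker) {
  if (!identical(dim(map$class_raster), dim(image$channels)[2:3]))
    stop_format("stroma map shape does not match image shape")
  idx <- frc_pixels(map)
  x <- get_channel(image, marker)[idx]
  tibble(marker = marker, mean_intensity = mean(x),
         median_intensity = stats::median(x), n_pixels = length(idx))
}

#' Fraction of FRC pixels positive for a marker
#'
#' Pixel-level positivity frequency over FRC-class pixels (e.g. FAP+ FRC
#' frequency). Pixels exactly at threshold count as positive. A per-object
#' variant over connected FRC components is available via `per_component`.
#'
#' @param image a [multiplex_image()].
#' @param map the matching `stroma_map`.
#' @param marker marker name.
#' @param positivity_threshold intensity threshold (same units as the
#'   channel); `"otsu"` to derive it from the FRC pixel intensities.
#' @param per_component if TRUE, report the fraction of connected FRC
#'   components whose mean intensity is positive instead.
#' @return tibble with `marker`, `threshold`, `fraction`, `n`.
#' @export
frc_positive_fraction <- function(image, map, marker,
                                  positivity_threshold = "otsu",
                                  per_component = FALSE) {
  idx <- frc_pixels(map)
  x <- get_channel(image, marker)
  thr <- if (identical(positivity_threshold, "otsu"))
    otsu_threshold(x[idx]) else positivity_threshold
  if (per_component) {
    lab <- EBImage::bwlabel(map$class_raster == 1L)
    means <- tapply(x[idx], lab[idx], mean)
    tibble(marker = marker, threshold = thr,
           fraction = mean(means >= thr), n = length(means))
  } else {
    tibble(marker = marker, threshold = thr,
           fraction = mean(x[idx] >= thr), n = length(idx))
  }
}

#' Binary FRC mask from a stroma map
#' @param map a `stroma_map`.
#' @return 0/1 integer matrix of FRC-class pixels.
#' @export
frc_mask <- function(map) {
  matrix(as.integer(map$class_raster == 1L), nrow(map$class_raster),
         ncol(map$class_raster))
}
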