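#' Distance from each cell to the FRC network
#'
#' Euclidean distance transform of the FRC-mask complement, sampled at cell
#' centroids (nearest pixel) and scaled to micrometres. Cells sitting on the
#' network get distance 0.
#'
#' @param cells cell table with centroid `row`/`col` in pixel coordinates of
#'   `mask`.
#' @param mask 0/1 FRC network raster sharing the cells' coordinate frame.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return the cell table with a `distance_um` column.
#' @export
distance_to_network <- function(cells, mask, pixel_size_um = 1) {
  check_columns(cells, c("row", "col"), "cell table")
  if (!any(mask != 0)) stop_degenerate("FRC mask is empty")
  edt <- EBImage::distmap(1 - (mask != 0))
  r <- pmin(pmax(round(cells$row), 1L), nrow(mask))
  c <- pmin(pmax(round(cells$col), 1L), ncol(mask))
  cells$distance_um <- as.numeric(edt[cbind(r, c)]) * pixel_size_um
  cells
}

#' Cluster x TFE distance profile
#'
#' Mean per-cell distance to the FRC network for every (CD8 cluster, TFE)
#' combination; combinations without cells are flagged `NA`, not zero.
#'
#' @param cells cell table with `distance_um`, `cd8_cluster`, `sample_id`.
#' @param assignment a [cluster_samples()] result (or a tibble with
#'   `sample_id` and `tfe`).
#' @return a `distance_profile` tibble: `cd8_cluster`, `tfe`,
#'   `mean_distance_um`, `n_cells`.
#' @export
cluster_distance_profile <- function(cells, assignment) {
  check_columns(cells, c("distance_um", "cd8_cluster", "sample_id"), "cell table")
  asg <- if (inherits(assignment, "tfe_assignment")) assignment$assignment
         else assignment
  df <- dplyr::inner_join(cells, asg, by = "sample_id")
  out <- df |>
    dplyr::group_by(.data$cd8_cluster, .data$tfe, .drop = FALSE) |>
    dplyr::summarise(mean_distance_um = mean(.data$distance_um),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(mean_distance_um = ifelse(.data$n_cells == 0, NA_real_,
                                            .data$mean_distance_um))
  class(out) <- c("distance_profile", class(out))
  out
}

#' Fraction of cells in contact with the network
#'
#' @param cells cell table with `distance_um`.
#' @param contact_threshold_um contact bound in micrometres (default 5).
#' @return tibble with `contact_threshold_um`, `fraction`, `n_cells`.
#' @export
contact_fraction <- function(cells, contact_threshold_um = 5) {
  check_columns(cells, "distance_um", "cell table")
  tibble(contact_threshold_um = contact_threshold_um,
         fraction = mean(cells$distance_um <= contact_threshold_um),
         n_cells = nrow(cells))
}

#' Flag spatially uncoupled TFEs
#'
#' A TFE is uncoupled when the cell-weighted mean CD8-to-network distance
#' over all its cells exceeds `cutoff_um` (10 um, the bound reported for
#' the poor-outcome environment).
#'
#' @param cells cell table with `distance_um` and `sample_id`.
#' @param assignment TFE assignment (as in [cluster_distance_profile()]).
#' @param cutoff_um uncoupling bound in micrometres.
#' @return tibble: `tfe`, `mean_distance_um`, `n_cells`, `uncoupled`.
#' @export
uncoupling_flag <- function(cells, assignment, cutoff_um = 10) {
  check_columns(cells, c("distance_um", "sample_id"), "cell table")
  asg <- if (inherits(assignment, "tfe_assignment")) assignment$assignment
         else assignment
  dplyr::inner_join(cells, asg, by = "sample_id") |>
    dplyr::group_by(.data$tfe) |>
    dplyr::summarise(mean_distance_um = mean(.data$distance_um),
                     n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(uncoupled = .data$mean_distance_um > cutoff_um)
}
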