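#' @import ggplot2
NULL

raster_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

#' Plot a stroma map
#'
#' @param map a `stroma_map`.
#' @return a ggplot raster of the FRC/LEC/BEC classes.
#' @export
plot_stroma_map <- function(map) {
  df <- raster_df(map$class_raster)
  df$class <- factor(stroma_classes[df$value + 1L], levels = stroma_classes)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$class)) +
    geom_raster() +
    scale_fill_manual(values = c(none = "grey15", FRC = "#E8D44D",
                                 LEC = "#4DB6E8", BEC = "#E84D4D")) +
    scale_y_reverse() + coord_fixed() +
    labs(x = NULL, y = NULL, fill = "compartment") + theme_minimal()
}

#' Plot gap-analysis circles over the fibre mask
#'
#' @param mask the binary fibre raster the gaps were computed on.
#' @param gaps a [gap_analysis()] result.
#' @return a ggplot.
#' @export
plot_gap_circles <- function(mask, gaps) {
  px <- attr(gaps, "pixel_size_um") %||% 1
  df <- raster_df(mask)
  th <- seq(0, 2 * pi, length.out = 60)
  circ <- purrr::imap(seq_len(nrow(gaps)), function(i, ...) {
    tibble(id = i, row = gaps$center_row[i] + gaps$radius_um[i] / px * sin(th),
           col = gaps$center_col[i] + gaps$radius_um[i] / px * cos(th))
  }) |> purrr::list_rbind()
  ggplot() +
    geom_raster(data = df[df$value > 0, ], aes(x = .data$col, y = .data$row),
                fill = "grey80") +
    geom_path(data = circ, aes(x = .data$col, y = .data$row,
                               group = .data$id, colour = factor(.data$id)),
              show.legend = FALSE) +
    scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL)
}

#' Heatmap of normalized median expression per cluster
#'
#' @param object a [median_expression_matrix()].
#' @param ... unused.
#' @return a ggplot tile heatmap.
#' @method autoplot median_expression_matrix
#' @export
autoplot.median_expression_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("cluster", "marker", "value")
  ggplot(df, aes(x = .data$marker, y = .data$cluster, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "median\n(normalized)") + theme_minimal()
}

#' Frequency heatmap with TFE annotation
#'
#' @param zm z-scored frequency tibble.
#' @param assignment a [cluster_samples()] result.
#' @return a ggplot tile heatmap, samples ordered by TFE.
#' @export
plot_frequency_heatmap <- function(zm, assignment) {
  df <- dplyr::inner_join(assignment$assignment, zm, by = "sample_id") |>
    dplyr::arrange(.data$tfe) |>
    dplyr::mutate(sample_id = factor(.data$sample_id,
                                     levels = unique(.data$sample_id))) |>
    tidyr::pivot_longer(-c("sample_id", "tfe"), names_to = "cluster",
                        values_to = "z") |>
    dplyr::mutate(cluster = factor(.data$cluster, levels = unique(.data$cluster)))
  ggplot(df, aes(x = .data$sample_id, y = .data$cluster, fill = .data$z)) +
    geom_tile() +
    facet_grid(~ .data$tfe, scales = "free_x", space = "free_x") +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    labs(x = "sample", y = NULL, fill = "z") +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}

#' Kaplan-Meier curves
#'
#' @param object a [km_estimate()] fit.
#' @param ... unused.
#' @return a ggplot of per-group survival step functions.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  start <- df |> dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, estimate = 1)
  df <- dplyr::bind_rows(start, df[, c("group", "time", "estimate")]) |>
    dplyr::arrange(.data$group, .data$time)
  ggplot(df, aes(x = .data$time, y = .data$estimate, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time (months)", y = "overall survival", colour = NULL) +
    theme_minimal()
}

#' Cluster x TFE distance heatmap
#'
#' @param profile a [cluster_distance_profile()] tibble.
#' @return a ggplot tile heatmap of mean distances (um).
#' @export
plot_distance_profile <- function(profile) {
  ggplot(profile, aes(x = .data$tfe, y = .data$cd8_cluster,
                      fill = .data$mean_distance_um)) +
    geom_tile() +
    scale_fill_viridis_c(na.value = "grey80") +
    labs(x = NULL, y = NULL, fill = "mean\ndistance (um)") + theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
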