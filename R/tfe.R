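#' Per-sample cluster frequency matrix
#'
#' Builds the sample x cluster frequency table underlying TFE discovery:
#' for each core, the fraction of CD8 cells in each phenotype cluster
#' (c1..cK), of FRC objects in each ligand gate (c11..c14), and of fibre
#' components in each shape class (c15..c18); fractions are computed per
#' block within each core (each block sums to 1) and then averaged across
#' the sample's cores, weighting cores equally. A sample with an empty
#' block receives uniform block values and a flag.
#'
#' @param cells clustered CD8 cell table (`sample_id`, `core_id`,
#'   `cd8_cluster`).
#' @param frc_cells gated FRC table (`ligand_gate`), or NULL to omit the block.
#' @param fibers fibre shape table (`shape_cluster`), or NULL to omit.
#' @return a `frequency_matrix`: tibble with `sample_id` and one column per
#'   cluster; attributes `blocks` (column names per block) and `imputed`
#'   (sample x block flags).
#' @export
build_frequency_matrix <- function(cells, frc_cells = NULL, fibers = NULL) {
  check_columns(cells, c("sample_id", "core_id", "cd8_cluster"), "cell table")
  block_freq <- function(df, label_col) {
    if (!is.factor(df[[label_col]]))
      stop_validation(sprintf("column '%s' must be a factor with fixed levels",
                              label_col))
    lv <- levels(df[[label_col]])
    df |>
      dplyr::count(.data$sample_id, .data$core_id, .data[[label_col]],
                   .drop = FALSE) |>
      dplyr::group_by(.data$sample_id, .data$core_id) |>
      dplyr::mutate(freq = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$sample_id, .data[[label_col]]) |>
      dplyr::summarise(freq = mean(.data$freq, na.rm = TRUE), .groups = "drop") |>
      tidyr::pivot_wider(names_from = dplyr::all_of(label_col),
                         values_from = "freq")
  }
  blocks <- list(cd8 = block_freq(cells, "cd8_cluster"))
  if (!is.null(frc_cells)) {
    check_columns(frc_cells, c("sample_id", "core_id", "ligand_gate"), "FRC table")
    blocks$ligand <- block_freq(frc_cells, "ligand_gate")
  }
  if (!is.null(fibers)) {
    check_columns(fibers, c("sample_id", "core_id", "shape_cluster"), "fibre table")
    blocks$shape <- block_freq(fibers, "shape_cluster")
  }
  out <- purrr::reduce(blocks, dplyr::full_join, by = "sample_id")
  block_cols <- lapply(blocks, function(b) setdiff(names(b), "sample_id"))
  imputed <- tibble(sample_id = out$sample_id)
  for (bn in names(block_cols)) {
    cols <- block_cols[[bn]]
    empty <- !stats::complete.cases(out[, cols])
    imputed[[bn]] <- empty
    if (any(empty)) {
      warn(sprintf("%d sample(s) had no objects in block '%s'; uniform-imputed",
                   sum(empty), bn))
      out[empty, cols] <- 1 / length(cols)
    }
  }
  out <- dplyr::arrange(out, .data$sample_id)
  attr(out, "blocks") <- block_cols
  attr(out, "imputed") <- imputed
  class(out) <- c("frequency_matrix", class(out))
  out
}

#' Z-score frequency columns across samples
#'
#' Per-column standardization (x - mean)/sd across samples; zero-variance
#' columns are set to 0 and flagged.
#'
#' @param fm a [build_frequency_matrix()] result (or any tibble whose first
#'   column is `sample_id` and the rest numeric).
#' @return the tibble with standardized columns; attribute `zero_variance`
#'   lists constant columns.
#' @export
zscore_columns <- function(fm) {
  if (nrow(fm) < 2) stop_degenerate("z-scoring needs at least 2 samples")
  cols <- setdiff(names(fm), "sample_id")
  zv <- character(0)
  for (cn in cols) {
    s <- stats::sd(fm[[cn]])
    if (!is.finite(s) || s == 0) {
      fm[[cn]] <- rep(0, nrow(fm)); zv <- c(zv, cn)
    } else {
      fm[[cn]] <- (fm[[cn]] - mean(fm[[cn]])) / s
    }
  }
  attr(fm, "zero_variance") <- zv
  fm
}

#' Hierarchically cluster samples into TFEs
#'
#' Ward-linkage agglomerative clustering on the Euclidean distances between
#' z-scored frequency profiles. The number of environments `k` is selected
#' by maximum mean silhouette width over `k_range` unless `k_fixed` is
#' given. TFE ids are renumbered deterministically: when `order_by` names
#' exhausted-associated columns, groups are sorted by descending mean
#' z-score over those columns, so TFE1 is the most exhausted-enriched group;
#' otherwise groups are sorted by first appearance in sample order.
#'
#' @param zm z-scored frequency tibble (see [zscore_columns()]).
#' @param k_range candidate group counts (clipped with a warning when larger
#'   than n - 1).
#' @param k_fixed fixed group count overriding selection.
#' @param order_by character vector of column names used to order TFE ids.
#' @param linkage hclust method (default `ward.D2`).
#' @return a `tfe_assignment`: list with `assignment` (tibble `sample_id`,
#'   `tfe`), `k`, `selection` (tibble `k`, `mean_silhouette`), `hclust`,
#'   `order_by`.
#' @export
cluster_samples <- function(zm, k_range = 2:8, k_fixed = NULL,
                            order_by = NULL, linkage = "ward.D2") {
  cols <- setdiff(names(zm), "sample_id")
  X <- as.matrix(zm[, cols])
  n <- nrow(X)
  if (n < 3) stop_degenerate("clustering needs at least 3 samples")
  if (max(k_range) > n - 1) {
    warn(sprintf("k_range clipped to 2..%d for %d samples", n - 1, n))
    k_range <- k_range[k_range <= n - 1]
  }
  d <- stats::dist(X)
  hc <- stats::hclust(d, method = linkage)
  selection <- tibble(k = integer(), mean_silhouette = numeric())
  if (is.null(k_fixed)) {
    sil <- map_dbl(k_range, function(k) {
      ct <- stats::cutree(hc, k)
      mean(cluster::silhouette(ct, d)[, "sil_width"])
    })
    selection <- tibble(k = as.integer(k_range), mean_silhouette = sil)
    k <- k_range[which.max(sil)]     # ties: smallest k
  } else {
    k <- k_fixed
  }
  ct <- stats::cutree(hc, k)
  # deterministic TFE numbering
  if (!is.null(order_by) && length(intersect(order_by, cols))) {
    sc <- rowMeans(X[, intersect(order_by, cols), drop = FALSE])
    grp_score <- tapply(sc, ct, mean)
    ord <- order(grp_score, decreasing = TRUE)
  } else {
    ord <- unique(ct)
  }
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  tfe <- factor(paste0("TFE", relabel[ct]), levels = paste0("TFE", seq_len(k)))
  structure(list(assignment = tibble(sample_id = zm$sample_id, tfe = tfe),
                 k = as.integer(k), selection = selection, hclust = hc,
                 order_by = order_by),
            class = "tfe_assignment")
}

#' @export
print.tfe_assignment <- function(x, ...) {
  cat(sprintf("<tfe_assignment> %d samples in %d TFEs: %s\n",
              nrow(x$assignment), x$k,
              paste(sprintf("%s=%d", levels(x$assignment$tfe),
                            table(x$assignment$tfe)), collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname cluster_samples
#' @param x a `tfe_assignment`.
#' @param ... unused.
#' @method tidy tfe_assignment
#' @export
tidy.tfe_assignment <- function(x, ...) x$assignment

#' @rdname cluster_samples
#' @method glance tfe_assignment
#' @export
glance.tfe_assignment <- function(x, ...) {
  tibble(k = x$k, n_samples = nrow(x$assignment),
         mean_silhouette = if (nrow(x$selection))
           x$selection$mean_silhouette[match(x$k, x$selection$k)] else NA_real_)
}

#' Characterize TFEs by mean z-scored cluster frequencies
#'
#' Per-TFE column means of the z-scored matrix, with per-TFE enrichment
#' ranks (1 = most enriched column).
#'
#' @param assignment a [cluster_samples()] result.
#' @param zm the z-scored frequency tibble it was fitted on.
#' @param top number of top enriched/depleted columns in the summary.
#' @return tibble: `tfe`, `column`, `mean_z`, `rank`; attribute `summary`
#'   holds one descriptive line per TFE.
#' @export
characterize_tfe <- function(assignment, zm, top = 3) {
  stopifnot(inherits(assignment, "tfe_assignment"))
  df <- dplyr::inner_join(assignment$assignment, zm, by = "sample_id")
  long <- tidyr::pivot_longer(df, -c("sample_id", "tfe"),
                              names_to = "column", values_to = "z")
  out <- long |>
    dplyr::group_by(.data$tfe, .data$column) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop_last") |>
    dplyr::mutate(rank = rank(-.data$mean_z, ties.method = "first")) |>
    dplyr::ungroup()
  summ <- out |>
    dplyr::group_by(.data$tfe) |>
    dplyr::summarise(line = sprintf(
      "%s: enriched %s; depleted %s", .data$tfe[1],
      paste(.data$column[order(-.data$mean_z)][seq_len(min(top, dplyr::n()))],
            collapse = ","),
      paste(.data$column[order(.data$mean_z)][seq_len(min(top, dplyr::n()))],
            collapse = ",")), .groups = "drop")
  attr(out, "summary") <- summ$line
  out
}
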