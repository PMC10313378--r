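#' Quantify single cells from a label mask
#'
#' Per-label morphology and marker statistics: area (pixel count scaled to
#' um^2), perimeter from the corner-corrected 8-connected boundary length
#' (Vossepoel-Smeulders weights plus a half-pixel dilation term), circularity
#' 4*pi*A/P^2 (capped at 1), centroid, and mean intensity per marker. Cells
#' are classed `CD8` when the mean CD8-channel intensity reaches the class
#' threshold, otherwise `FRC` when PDPN-high, otherwise `other`.
#'
#' @param image a [multiplex_image()].
#' @param label_mask integer matrix, 0 = background; labels need not be
#'   contiguous; shape must match the image.
#' @param class_thresholds optional named vector with `CD8` and/or `PDPN`
#'   mean-intensity thresholds; defaults to Otsu over per-cell means.
#' @return a cell table (tibble): `cell_id`, `sample_id`, `core_id`, `row`,
#'   `col`, `area_um2`, `perimeter_um`, `circularity`, one column per
#'   marker (mean intensity), `class`.
#' @export
quantify_cells <- function(image, label_mask, class_thresholds = NULL) {
  if (!identical(dim(label_mask), dim(image$channels)[2:3]))
    stop_format(sprintf("mask shape (%s) does not match image shape (%s)",
                        paste(dim(label_mask), collapse = "x"),
                        paste(dim(image$channels)[2:3], collapse = "x")))
  px <- image$pixel_size_um
  labs <- sort(unique(label_mask[label_mask > 0]))
  if (!length(labs))
    return(tibble(cell_id = integer(), sample_id = character(),
                  core_id = character(), row = numeric(), col = numeric(),
                  area_um2 = numeric(), perimeter_um = numeric(),
                  circularity = numeric(), class = character()))
  idx <- which(label_mask > 0, arr.ind = TRUE)
  lv <- label_mask[idx]
  f <- factor(lv, levels = labs)
  area_px <- as.integer(table(f))
  cen_r <- tapply(idx[, 1], f, mean)
  cen_c <- tapply(idx[, 2], f, mean)
  lin <- which(label_mask > 0)
  means <- matrix(0, length(labs), nrow(image$panel),
                  dimnames = list(NULL, image$panel$marker))
  for (mk in image$panel$marker) {
    ch <- get_channel(image, mk)
    means[, mk] <- as.numeric(tapply(ch[lin], f, mean))
  }
  per_px <- perimeter_per_label(label_mask, labs)
  perimeter_um <- per_px * px
  area_um2 <- area_px * px^2
  circ <- pmin(4 * pi * area_px / pmax(per_px, 1e-9)^2, 1)
  out <- tibble(cell_id = as.integer(labs), sample_id = image$sample_id,
                core_id = image$core_id, row = as.numeric(cen_r),
                col = as.numeric(cen_c), area_um2 = area_um2,
                perimeter_um = perimeter_um, circularity = circ) |>
    dplyr::bind_cols(as_tibble(means))
  if (is.null(class_thresholds)) {
    # derive class thresholds from whole-channel pixel intensities (bimodal
    # background/foreground), not per-cell means which may be unimodal
    class_thresholds <- c(
      CD8 = if ("CD8" %in% image$panel$marker)
        otsu_threshold(get_channel(image, "CD8")) else Inf,
      PDPN = if ("PDPN" %in% image$panel$marker)
        otsu_threshold(get_channel(image, "PDPN")) else Inf)
  }
  out$class <- classify_cells(out, class_thresholds)
  out
}

# boundary length per label: corner-corrected chain-code estimator
perimeter_per_label <- function(label_mask, labs) {
  # relabel to contiguous so ocontour indexes align
  rel <- matrix(match(label_mask, c(0, labs), nomatch = 1L) - 1L,
                nrow(label_mask), ncol(label_mask))
  ctr <- EBImage::ocontour(rel)
  sapply(seq_along(labs), function(i) {
    oc <- ctr[[i]]
    if (is.null(oc) || nrow(oc) < 2) return(pi)   # single pixel
    d <- diff(rbind(oc, oc[1, ]))
    steps <- sqrt(rowSums(d^2))
    n_even <- sum(abs(steps - 1) < 1e-9)
    n_odd <- sum(steps > 1.2)
    ang <- atan2(d[, 2], d[, 1])
    n_corner <- sum(abs(diff(c(ang, ang[1]))) > 1e-9)
    0.980 * n_even + 1.406 * n_odd - 0.091 * n_corner + pi
  })
}

classify_cells <- function(cells, class_thresholds = NULL) {
  get_thr <- function(mk) {
    if (!is.null(class_thresholds) && mk %in% names(class_thresholds))
      return(class_thresholds[[mk]])
    if (!mk %in% names(cells)) return(Inf)
    otsu_threshold(cells[[mk]])
  }
  cls <- rep("other", nrow(cells))
  if ("PDPN" %in% names(cells)) cls[cells$PDPN >= get_thr("PDPN")] <- "FRC"
  if ("CD8" %in% names(cells)) cls[cells$CD8 >= get_thr("CD8")] <- "CD8"
  cls
}

#' Cell density per tissue area
#'
#' @param cells a cell table.
#' @param tissue_area_mm2 denominator area in mm^2 (> 0).
#' @param class cell class to count (default CD8).
#' @return tibble with `class`, `n_cells`, `density_per_mm2`.
#' @export
cell_density <- function(cells, tissue_area_mm2, class = "CD8") {
  if (!is.numeric(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop_degenerate("tissue_area_mm2 must be > 0")
  n <- if ("class" %in% names(cells)) sum(cells$class == class) else nrow(cells)
  tibble(class = class, n_cells = n, density_per_mm2 = n / tissue_area_mm2)
}

#' Arcsinh-normalize marker intensities
#'
#' The cytometry-standard transform: `arcsinh(x / cofactor)`, then a
#' per-marker linear rescale mapping the `pmin` percentile to 0 and the
#' `pmax` percentile to 1, clipped to \[0,1\]. Rank order is preserved;
#' zero-variance markers map to 0.
#'
#' @param cells a cell table.
#' @param markers columns to normalize (default the six phenotyping markers
#'   present in the table).
#' @param cofactor arcsinh cofactor (default 5, the IMC convention).
#' @param pmin,pmax rescaling percentiles in \[0,1\] with `pmin < pmax`.
#' @return the table with the marker columns replaced by normalized values;
#'   parameters recorded in attribute `normalization`.
#' @export
normalize_markers <- function(cells, markers = intersect(cd8_markers, names(cells)),
                              cofactor = 5, pmin = 0.01, pmax = 0.99) {
  if (pmin >= pmax) stop_param("pmin must be < pmax")
  check_columns(cells, markers, "cell table")
  for (mk in markers) {
    x <- asinh(cells[[mk]] / cofactor)
    q <- stats::quantile(x, c(pmin, pmax), na.rm = TRUE, names = FALSE)
    cells[[mk]] <- if (diff(q) <= 0) rep(0, length(x)) else
      pmin(pmax((x - q[1]) / (q[2] - q[1]), 0), 1)
  }
  attr(cells, "normalization") <- list(markers = markers, cofactor = cofactor,
                                       pmin = pmin, pmax = pmax)
  cells
}

# chunked brute-force k-nearest-neighbour indices (no self)
knn_indices <- function(X, k, chunk = 512L) {
  n <- nrow(X)
  if (k >= n) stop_degenerate("k_nn must be smaller than the number of cells")
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * X[s:e, , drop = FALSE] %*% t(X)
    for (i in seq_len(e - s + 1L)) {
      d2[i, s + i - 1L] <- Inf
      out[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

#' PhenoGraph-style clustering of CD8 cells
#'
#' Builds a k-nearest-neighbour graph on the normalized marker space
#' (Euclidean), weights each edge by the Jaccard overlap of the two cells'
#' neighbour sets, and partitions the graph by Louvain modularity
#' optimization under a fixed seed. Cluster labels are renumbered by
#' descending cluster size (c1 is the largest), making the labeling
#' invariant to cell order.
#'
#' @param cells a cell table with normalized marker columns (see
#'   [normalize_markers()]); restrict to CD8 cells before calling.
#' @param markers marker columns used as coordinates.
#' @param k_nn neighbours per cell (default 30).
#' @param seed community-detection seed.
#' @return the table with a `cd8_cluster` factor column (c1..cK); attribute
#'   `clustering` records k, modularity and parameters.
#' @export
cluster_phenotypes <- function(cells, markers = intersect(cd8_markers, names(cells)),
                               k_nn = 30L, seed = 1L) {
  check_columns(cells, markers, "cell table")
  n <- nrow(cells)
  if (n < k_nn + 1) stop_degenerate(sprintf(
    "need at least k_nn + 1 = %d cells, got %d", k_nn + 1, n))
  X <- as.matrix(cells[, markers])
  if (nrow(unique(X)) == 1L) {
    cells$cd8_cluster <- factor(rep("c1", n), levels = "c1")
    attr(cells, "clustering") <- list(k = 1L, modularity = NA_real_,
                                      k_nn = k_nn, seed = seed)
    return(cells)
  }
  # canonicalize cell order by marker content so the partition is invariant
  # to the input row order (community detection iterates in graph order)
  ord <- do.call(order, as.data.frame(X))
  X <- X[ord, , drop = FALSE]
  nn <- knn_indices(X, k_nn)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k_nn), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  # candidate edges: union of directed kNN links
  U <- A + Matrix::t(A)
  tri <- Matrix::which(U != 0, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  common <- Matrix::tcrossprod(A)   # shared-neighbour counts
  cm <- common[tri]
  jac <- cm / (2 * k_nn - cm)
  keep <- jac > 0
  if (!any(keep)) {   # no shared-neighbour structure at all
    cells$cd8_cluster <- factor(rep("c1", n), levels = "c1")
    attr(cells, "clustering") <- list(k = 1L, modularity = NA_real_,
                                      k_nn = k_nn, seed = seed)
    return(cells)
  }
  g <- igraph::graph_from_edgelist(tri[keep, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(g, weights = jac[keep]))
  memb_sorted <- igraph::membership(cl)
  memb <- integer(n); memb[ord] <- memb_sorted
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  # c11-c18 are reserved for FRC ligand gates and fibre shape classes, so a
  # partition with more than 10 communities continues at c19
  lab_pool <- c(paste0("c", 1:10), paste0("c", 18 + seq_len(max(0, length(sizes) - 10))))
  lab <- lab_pool[relabel[as.character(memb)]]
  cells$cd8_cluster <- factor(lab, levels = lab_pool[seq_along(sizes)])
  attr(cells, "clustering") <- list(k = length(sizes),
                                    modularity = igraph::modularity(cl),
                                    k_nn = k_nn, seed = seed)
  cells
}

#' Normalized median expression per cluster
#'
#' Per-cluster, per-marker median of the normalized intensities, followed by
#' a per-marker min-max rescale across clusters (as drawn in cluster
#' heatmaps): each marker column spans \[0,1\] when it varies between
#' clusters, and is 0 everywhere otherwise. Empty clusters are excluded with
#' a warning.
#'
#' @param cells a clustered cell table.
#' @param markers marker columns.
#' @param cluster_col name of the cluster label column.
#' @return a `median_expression_matrix`: numeric matrix (clusters x markers)
#'   with attribute `counts` (cells per cluster).
#' @export
median_expression_matrix <- function(cells, markers = intersect(cd8_markers, names(cells)),
                                     cluster_col = "cd8_cluster") {
  check_columns(cells, c(markers, cluster_col), "cell table")
  f <- cells[[cluster_col]]
  if (anyNA(f)) stop_validation("every cell must carry a cluster label")
  if (is.factor(f) && any(table(f) == 0)) {
    warn("dropping empty cluster level(s)")
    f <- droplevels(f)
  }
  med <- sapply(markers, function(mk)
    as.numeric(tapply(cells[[mk]], f, stats::median)))
  med <- matrix(med, ncol = length(markers),
                dimnames = list(levels(factor(f)), markers))
  scaled <- apply(med, 2, function(v) {
    if (diff(range(v)) <= 0) rep(0, length(v)) else
      (v - min(v)) / (max(v) - min(v))
  })
  scaled <- matrix(scaled, nrow = nrow(med), dimnames = dimnames(med))
  structure(scaled, counts = as.integer(table(f)),
            class = c("median_expression_matrix", "matrix", "array"))
}

#' Assign phenotype identities to CD8 clusters
#'
#' Maps each cluster's normalized median profile to one of the four CD8
#' phenotype identities using the checkpoint-vs-granzyme-B logic: both high
#' = terminally exhausted; both low = nonactivated; checkpoints above GrB
#' by `margin` = progenitor exhausted; GrB above checkpoints = cytotoxic;
#' anything else is flagged indeterminate. The checkpoint score is the mean
#' of the five checkpoint medians. Rules are tested in this precedence
#' order on the \[0,1\] normalized scale.
#'
#' @param mem a [median_expression_matrix()] containing the five checkpoint
#'   markers and GrB.
#' @param low_thr,high_thr,margin decision constants on the normalized scale.
#' @return tibble: `cluster`, `ckpt`, `grb`, `identity`.
#' @export
assign_phenotype_identity <- function(mem, low_thr = 0.35, high_thr = 0.65,
                                      margin = 0.1) {
  need <- c(checkpoint_markers, "GrB")
  if (!all(need %in% colnames(mem)))
    stop_panel(sprintf("expression matrix lacks marker(s): %s",
                       paste(setdiff(need, colnames(mem)), collapse = ", ")))
  ckpt <- rowMeans(mem[, checkpoint_markers, drop = FALSE])
  grb <- mem[, "GrB"]
  identity <- dplyr::case_when(
    ckpt >= high_thr & grb >= high_thr ~ "terminally_exhausted",
    ckpt < low_thr & grb < low_thr ~ "nonactivated",
    ckpt >= grb + margin ~ "progenitor_exhausted",
    grb >= ckpt + margin ~ "cytotoxic",
    TRUE ~ "indeterminate")
  tibble(cluster = rownames(mem), ckpt = as.numeric(ckpt),
         grb = as.numeric(grb), identity = identity)
}

#' Gate FRC objects on PD-1 ligand expression (clusters c11-c14)
#'
#' Double-gates FRC records on PD-L1 and PD-L2 positivity (per-marker Otsu
#' threshold by default): the four gates -/-, +/-, -/+, +/+ map to fixed
#' labels c11, c12, c13, c14.
#'
#' @param frc_cells tibble of FRC records with `PD-L1` and `PD-L2` columns.
#' @param thresholds optional named vector of fixed thresholds.
#' @return the table with a `ligand_gate` factor column (levels c11..c14);
#'   thresholds recorded in attribute `ligand_thresholds`.
#' @export
frc_ligand_clusters <- function(frc_cells, thresholds = NULL) {
  if (!nrow(frc_cells)) stop_degenerate("no FRC records to gate")
  check_columns(frc_cells, c("PD-L1", "PD-L2"), "FRC table")
  thr <- c(
    `PD-L1` = if (!is.null(thresholds) && "PD-L1" %in% names(thresholds))
      unname(thresholds[["PD-L1"]]) else otsu_threshold(frc_cells[["PD-L1"]]),
    `PD-L2` = if (!is.null(thresholds) && "PD-L2" %in% names(thresholds))
      unname(thresholds[["PD-L2"]]) else otsu_threshold(frc_cells[["PD-L2"]]))
  p1 <- frc_cells[["PD-L1"]] >= thr[["PD-L1"]]
  p2 <- frc_cells[["PD-L2"]] >= thr[["PD-L2"]]
  gate <- dplyr::case_when(!p1 & !p2 ~ "c11", p1 & !p2 ~ "c12",
                           !p1 & p2 ~ "c13", TRUE ~ "c14")
  frc_cells$ligand_gate <- factor(gate, levels = paste0("c", 11:14))
  attr(frc_cells, "ligand_thresholds") <- thr
  frc_cells
}
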