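make_cell_image <- function(mask_builder) {
  mask <- mask_builder
  ch <- matrix(1, nrow(mask), ncol(mask))
  img <- multiplex_image(list(ch), marker_panel("CD8"))
  list(img = img, mask = mask)
}

test_that("circularity hits the disk, line and square limits", {
  disk <- make_disk(20)
  f <- make_cell_image(disk)
  cells <- quantify_cells(f$img, f$mask, class_thresholds = c(CD8 = 0.5))
  expect_gte(cells$circularity, 0.95)
  expect_equal(cells$area_um2, sum(disk))

  line <- matrix(0L, 5, 64); line[3, 3:62] <- 1L
  f <- make_cell_image(line)
  expect_lte(quantify_cells(f$img, f$mask)$circularity, 0.1)

  sq <- matrix(0L, 25, 25); sq[3:23, 3:23] <- 1L
  f <- make_cell_image(sq)
  # analytic oracle: 4*pi*A/P^2 with ideal perimeter P = 4*21
  expect_equal(quantify_cells(f$img, f$mask)$circularity,
               4 * pi * 441 / 84^2, tolerance = 0.08 / (pi / 4))
})

test_that("quantify_cells validates shapes and reports per-label means", {
  mask <- matrix(0L, 6, 6); mask[2:3, 2:3] <- 4L; mask[5, 5] <- 9L
  ch <- matrix(seq_len(36), 6, 6)
  img <- multiplex_image(list(ch), marker_panel("GrB"))
  cells <- quantify_cells(img, mask)
  expect_identical(cells$cell_id, c(4L, 9L))
  expect_equal(cells$GrB[1], mean(ch[mask == 4L]))
  expect_equal(cells$GrB[2], ch[5, 5])
  expect_error(quantify_cells(img, matrix(0L, 5, 5)),
               class = "tilfrc_format_error")
})

test_that("cell density is count over area", {
  cells <- tibble::tibble(class = rep("CD8", 50))
  expect_equal(cell_density(cells, 0.5)$density_per_mm2, 100)
  expect_equal(cell_density(cells[0, ], 2)$density_per_mm2, 0)
  expect_error(cell_density(cells, 0), class = "tilfrc_degenerate_input_error")
})

test_that("marker normalization rescales percentiles and preserves ranks", {
  df <- tibble::tibble(GrB = c(0, 1, 5, 20, 100), `PD-1` = rep(0, 5))
  out <- normalize_markers(df, c("GrB", "PD-1"), cofactor = 5,
                           pmin = 0, pmax = 1)
  expect_equal(out$`PD-1`, rep(0, 5))           # zero-variance guard
  expect_equal(max(out$GrB), 1)                 # pmax percentile -> 1
  expect_equal(min(out$GrB), 0)
  expect_identical(order(out$GrB), order(df$GrB))
  expect_error(normalize_markers(df, "GrB", pmin = 0.9, pmax = 0.1),
               class = "tilfrc_parameter_error")
})

test_that("well-separated phenotypes are recovered as exact communities", {
  df <- planted_marker_cells(n_per = 40, centers = c(0.1, 0.5, 0.9), sd = 0.01)
  out <- cluster_phenotypes(df, k_nn = 30, seed = 2)
  expect_identical(nlevels(out$cd8_cluster), 3L)
  expect_equal(adjusted_rand_index(out$cd8_cluster, df$planted), 1)
})

test_that("clustering is deterministic and order-invariant after renumbering", {
  df <- planted_marker_cells(n_per = 40, centers = c(0.2, 0.8), sd = 0.02)
  df <- df[-(1:15), ]   # unequal sizes so size-based renumbering is unambiguous
  a <- cluster_phenotypes(df, k_nn = 20, seed = 3)
  b <- cluster_phenotypes(df, k_nn = 20, seed = 3)
  expect_identical(a$cd8_cluster, b$cd8_cluster)

  perm <- withr::with_seed(9, sample(nrow(df)))
  c_ <- cluster_phenotypes(df[perm, ], k_nn = 20, seed = 3)
  expect_identical(as.character(c_$cd8_cluster),
                   as.character(a$cd8_cluster[perm]))
})

test_that("identical cells collapse to one community; too few cells error", {
  mk <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
  df <- tibble::as_tibble(matrix(0.5, 40, 6, dimnames = list(NULL, mk)))
  out <- cluster_phenotypes(df, k_nn = 10, seed = 1)
  expect_identical(nlevels(out$cd8_cluster), 1L)
  expect_error(cluster_phenotypes(df[1:5, ], k_nn = 10),
               class = "tilfrc_degenerate_input_error")
})

test_that("median expression matrix equals the brute-force medians, rescaled", {
  mk <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
  df <- planted_marker_cells(n_per = 50, centers = c(0.2, 0.6), sd = 0.05)
  df$cd8_cluster <- factor(paste0("c", df$planted))
  mem <- median_expression_matrix(df)
  for (m in mk) {
    med <- tapply(df[[m]], df$cd8_cluster, stats::median)
    scaled <- (med - min(med)) / (max(med) - min(med))
    expect_equal(unname(mem[, m]), as.numeric(scaled), tolerance = 1e-12)
  }
  # two clusters with medians 2 and 6 rescale to 0 and 1
  df2 <- tibble::tibble(GrB = c(2, 2, 6, 6),
                        cd8_cluster = factor(c("c1", "c1", "c2", "c2")))
  expect_equal(unname(median_expression_matrix(df2, "GrB")[, 1]), c(0, 1))
  # single cluster, constant marker -> 0 under the zero-variance guard
  df3 <- tibble::tibble(GrB = c(4, 4), cd8_cluster = factor(c("c1", "c1")))
  expect_equal(unname(median_expression_matrix(df3, "GrB")[, 1]), 0)
})

test_that("identity rules follow the checkpoint/GrB decision table", {
  mk <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
  mem <- rbind(c(rep(0.8, 5), 0.8),   # both high
               c(rep(0.2, 5), 0.2),   # both low
               c(rep(0.7, 5), 0.3),   # checkpoints >> GrB
               c(rep(0.3, 5), 0.7),   # GrB >> checkpoints
               c(rep(0.5, 5), 0.52))  # inside the margin
  colnames(mem) <- mk; rownames(mem) <- paste0("c", 1:5)
  out <- assign_phenotype_identity(mem)
  expect_identical(out$identity,
                   c("terminally_exhausted", "nonactivated",
                     "progenitor_exhausted", "cytotoxic", "indeterminate"))
  expect_error(assign_phenotype_identity(mem[, 1:5]),
               class = "tilfrc_panel_error")
})

test_that("identity assignment is invariant to a global intensity rescale", {
  # two well-separated archetypes at realistic raw counts; compare the
  # per-cell identity labels after the full normalize/cluster/assign path
  mk <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
  df <- withr::with_seed(10, {
    lo <- matrix(stats::rlnorm(40 * 6, log(2), 0.2), 40, 6,
                 dimnames = list(NULL, mk))
    hi <- matrix(stats::rlnorm(25 * 6, log(30), 0.2), 25, 6,
                 dimnames = list(NULL, mk))
    d <- tibble::as_tibble(rbind(lo, hi))
    d$sample_id <- "s1"; d$core_id <- "c1"; d$cell_id <- seq_len(nrow(d))
    d
  })
  run <- function(scale) {
    d <- df
    for (m in mk) d[[m]] <- d[[m]] * scale
    d <- normalize_markers(d)
    d <- cluster_phenotypes(d, k_nn = 30, seed = 1)
    ident <- assign_phenotype_identity(median_expression_matrix(d))
    ident$identity[match(d$cd8_cluster, ident$cluster)]
  }
  expect_identical(run(1), run(137))
})

test_that("ligand gates match the brute-force 2x2 tally", {
  frc <- tibble::tibble(`PD-L1` = c(0, 9, 0, 9, 8), `PD-L2` = c(0, 0, 9, 9, 9))
  out <- frc_ligand_clusters(frc, thresholds = c(`PD-L1` = 5, `PD-L2` = 5))
  expect_identical(as.character(out$ligand_gate),
                   c("c11", "c12", "c13", "c14", "c14"))
  tally <- table(out$ligand_gate)
  expect_identical(as.integer(tally),
                   c(sum(frc$`PD-L1` < 5 & frc$`PD-L2` < 5),
                     sum(frc$`PD-L1` >= 5 & frc$`PD-L2` < 5),
                     sum(frc$`PD-L1` < 5 & frc$`PD-L2` >= 5),
                     sum(frc$`PD-L1` >= 5 & frc$`PD-L2` >= 5)))
  # all-zero ligands gate to c11 under fixed thresholds
  frc0 <- tibble::tibble(`PD-L1` = rep(0, 4), `PD-L2` = rep(0, 4))
  out0 <- frc_ligand_clusters(frc0, thresholds = c(`PD-L1` = 1, `PD-L2` = 1))
  expect_true(all(out0$ligand_gate == "c11"))
  expect_error(frc_ligand_clusters(frc0[0, ]),
               class = "tilfrc_degenerate_input_error")
})

test_that("planted archetypes are recovered with >= 95% cell-level agreement", {
  cfg <- cohort_config(n_samples = 1, cores_per_sample = 1,
                       n_cd8_per_core = 2000, n_frc_per_core = 1,
                       n_fibers_per_core = 1, mixing_noise_sd = 0, seed = 44,
                       archetype_library = default_tfe_archetypes()["TFE3"])
  co <- generate_cohort(cfg)
  cells <- normalize_markers(co$cells) |> cluster_phenotypes(seed = 2)
  ident <- assign_phenotype_identity(median_expression_matrix(cells))
  pred <- ident$identity[match(cells$cd8_cluster, ident$cluster)]
  expect_gte(mean(pred == cells$archetype), 0.95)
})
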