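planted_frequency_cohort <- function(n_samples = 24, n_per_core = 60,
                                     noise = 0.02, seed = 1) {
  co <- generate_cohort(cohort_config(
    n_samples = n_samples, n_cd8_per_core = n_per_core,
    n_frc_per_core = 40, n_fibers_per_core = 30,
    mixing_noise_sd = noise, seed = seed))
  co
}

test_that("frequency matrix computes per-core fractions averaged over cores", {
  cells <- tibble::tibble(
    sample_id = "s1",
    core_id = rep(c("core1", "core2"), c(10, 10)),
    cd8_cluster = factor(c(rep("c1", 4), rep("c2", 6),    # core1: 0.4 / 0.6
                           rep("c1", 2), rep("c2", 8)),   # core2: 0.2 / 0.8
                         levels = c("c1", "c2")))
  fm <- build_frequency_matrix(cells)
  expect_equal(fm$c1, 0.3)     # mean of 0.4 and 0.2
  expect_equal(fm$c2, 0.7)
  expect_equal(fm$c1 + fm$c2, 1)
})

test_that("single-core block sums are 1 and labels are validated", {
  cells <- tibble::tibble(sample_id = rep(c("a", "b"), each = 10),
                          core_id = "core1",
                          cd8_cluster = factor(
                            rep(c("c1", "c2", "c1", "c3"), c(4, 6, 5, 5)),
                            levels = c("c1", "c2", "c3")))
  fm <- build_frequency_matrix(cells)
  expect_equal(rowSums(fm[, c("c1", "c2", "c3")]), c(1, 1),
               ignore_attr = TRUE)
  expect_equal(fm$c1[fm$sample_id == "a"], 0.4)
  bad <- cells; bad$cd8_cluster <- as.character(bad$cd8_cluster)
  expect_error(build_frequency_matrix(bad), class = "tilfrc_validation_error")
})

test_that("z-scoring matches the direct formula and guards degenerate input", {
  fm <- tibble::tibble(sample_id = c("a", "b", "c"),
                       c1 = c(0.2, 0.5, 0.8), c2 = rep(0.4, 3))
  zm <- zscore_columns(fm)
  expect_equal(zm$c1, (fm$c1 - mean(fm$c1)) / stats::sd(fm$c1))
  expect_equal(mean(zm$c1), 0)
  expect_equal(stats::sd(zm$c1), 1)
  expect_equal(zm$c2, rep(0, 3))                  # constant column -> 0
  expect_identical(attr(zm, "zero_variance"), "c2")
  expect_error(zscore_columns(fm[1, ]), class = "tilfrc_degenerate_input_error")
})

test_that("planted archetypes are recovered with silhouette-selected k", {
  co <- planted_frequency_cohort(seed = 6)
  cells <- co$cells
  cells$cd8_cluster <- factor(paste0("c", as.integer(
    factor(cells$archetype, levels = names(default_phenotype_archetypes())))))
  frc <- frc_ligand_clusters(co$frc_cells)
  fib <- classify_fiber_shapes(co$fibers, seed = 1)
  zm <- zscore_columns(build_frequency_matrix(cells, frc, fib))
  asg <- cluster_samples(zm, order_by = c("c2", "c4"))
  expect_identical(asg$k, 4L)
  truth <- dplyr::distinct(co$samples, .data$sample_id, .data$tfe_true)
  j <- dplyr::inner_join(tidy(asg), truth, by = "sample_id")
  expect_equal(adjusted_rand_index(j$tfe, j$tfe_true), 1)
})

test_that("k_fixed forces the group count; permutation leaves the partition", {
  co <- planted_frequency_cohort(n_samples = 12, seed = 8)
  cells <- co$cells
  cells$cd8_cluster <- factor(paste0("c", as.integer(
    factor(cells$archetype, levels = names(default_phenotype_archetypes())))))
  zm <- zscore_columns(build_frequency_matrix(cells))
  asg2 <- cluster_samples(zm, k_fixed = 2)
  expect_identical(asg2$k, 2L)
  expect_identical(nlevels(tidy(asg2)$tfe), 2L)

  perm <- withr::with_seed(3, sample(nrow(zm)))
  asg_a <- cluster_samples(zm, k_fixed = 4, order_by = "c2")
  asg_b <- cluster_samples(zm[perm, ], k_fixed = 4, order_by = "c2")
  j <- dplyr::inner_join(tidy(asg_a), tidy(asg_b), by = "sample_id")
  expect_identical(as.character(j$tfe.x), as.character(j$tfe.y))
})

test_that("TFE characterization satisfies the z-score identities", {
  zm <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                       c1 = c(2, 1.5, -0.5, -1, -1, -1),
                       c2 = c(-1, -1, 2, 1, -0.5, -0.5))
  zm <- zscore_columns(zm)
  asg <- cluster_samples(zm, k_fixed = 3)
  ch <- characterize_tfe(asg, zm)
  # a TFE with one sample reports exactly that sample's row
  sizes <- table(tidy(asg)$tfe)
  if (any(sizes == 1)) {
    solo <- names(sizes)[sizes == 1][1]
    sid <- tidy(asg)$sample_id[tidy(asg)$tfe == solo][1]
    expect_equal(ch$mean_z[ch$tfe == solo & ch$column == "c1"],
                 zm$c1[zm$sample_id == sid])
  }
  # size-weighted mean of per-TFE means is 0 per column
  w <- as.integer(sizes[as.character(ch$tfe)])
  for (cn in c("c1", "c2")) {
    sub <- ch[ch$column == cn, ]
    expect_equal(sum(sub$mean_z * sizes[as.character(sub$tfe)]) / sum(sizes), 0,
                 tolerance = 1e-12)
  }
})

test_that("end-to-end archetype recovery averages ARI >= 0.9 over 50 seeds", {
  aris <- vapply(1:50, function(sd) {
    co <- generate_cohort(cohort_config(
      n_samples = 16, n_cd8_per_core = 60, n_frc_per_core = 40,
      n_fibers_per_core = 30, mixing_noise_sd = 0.05, seed = 100 + sd))
    cells <- normalize_markers(co$cells) |>
      cluster_phenotypes(k_nn = 30, seed = 1)
    frc <- frc_ligand_clusters(co$frc_cells)
    fib <- classify_fiber_shapes(co$fibers, seed = 1)
    zm <- zscore_columns(build_frequency_matrix(cells, frc, fib))
    asg <- cluster_samples(zm, k_fixed = 4)
    truth <- dplyr::distinct(co$samples, .data$sample_id, .data$tfe_true)
    j <- dplyr::inner_join(tidy(asg), truth, by = "sample_id")
    adjusted_rand_index(j$tfe, j$tfe_true)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  withr::with_seed(5, {
    for (i in 1:5) {
      a <- sample(1:4, 60, replace = TRUE)
      b <- sample(1:3, 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)), 0, tolerance = 1)
})
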