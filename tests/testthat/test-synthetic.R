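test_that("network generator: empty density, determinism, parameter errors", {
  p0 <- network_params(field_size_px = c(64, 64), fiber_density = 0, seed = 9)
  net0 <- generate_frc_network(p0)
  expect_true(all(net0$raster == 0L))
  expect_identical(net0$truth$n_branches, 0L)

  p <- network_params(field_size_px = c(128, 128), seed = 4)
  expect_identical(generate_frc_network(p)$raster, generate_frc_network(p)$raster)

  expect_error(network_params(field_size_px = c(0, 64)),
               class = "tilfrc_parameter_error")
  expect_error(network_params(fiber_width_px = 2),
               class = "tilfrc_parameter_error")
})

test_that("measured branch count tracks the generative graph within 15%", {
  net <- generate_frc_network(network_params(seed = 3))
  bs <- branch_statistics(skeletonize_network(net$raster, 1, 3))
  expect_gt(bs$n_branches, 0.85 * net$truth$n_branches)
  expect_lt(bs$n_branches, 1.15 * net$truth$n_branches)
})

test_that("sample image generator honours placement modes and cell counts", {
  lib <- default_tfe_archetypes()
  np <- network_params(seed = 11)          # default 512^2 core

  sim0 <- generate_sample_image(np, lib$TFE4, n_cd8 = 0, seed = 1)
  expect_identical(nrow(sim0$truth_cells), 0L)
  expect_true(all(sim0$label_mask == 0L))

  # uncoupled: constraint enforced exactly against the ground-truth mask
  sim_u <- generate_sample_image(np, lib$TFE1, n_cd8 = 60, seed = 2)
  d <- distance_to_network(sim_u$truth_cells, sim_u$frc_mask, 1)
  expect_gte(min(d$distance_um), 12)

  # coupled: most cells hug the network (brute-force nearest-pixel oracle)
  sim_c <- generate_sample_image(np, lib$TFE4, n_cd8 = 200, seed = 2)
  idx <- which(sim_c$frc_mask == 1L, arr.ind = TRUE)
  brute <- vapply(seq_len(200), function(i) {
    sqrt(min((idx[, 1] - sim_c$truth_cells$row[i])^2 +
               (idx[, 2] - sim_c$truth_cells$col[i])^2))
  }, numeric(1))
  expect_gte(mean(brute <= 5), 0.6)

  expect_error(generate_sample_image(np, lib$TFE4, n_cd8 = -1),
               class = "tilfrc_parameter_error")
})

test_that("sample image generation is bit-identical under the same seed", {
  lib <- default_tfe_archetypes()
  np <- network_params(field_size_px = c(128, 128), seed = 5)
  a <- generate_sample_image(np, lib$TFE2, n_cd8 = 30, seed = 7)
  b <- generate_sample_image(np, lib$TFE2, n_cd8 = 30, seed = 7)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$label_mask, b$label_mask)
  expect_identical(a$truth_cells, b$truth_cells)
})

test_that("cohort assignment is round-robin and censoring behaves", {
  cfg <- cohort_config(n_samples = 8, cores_per_sample = 1, n_cd8_per_core = 5,
                       n_frc_per_core = 2, n_fibers_per_core = 2, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(as.integer(table(co$clinical$tfe_true)), rep(2L, 4))

  cfg1 <- cohort_config(n_samples = 20, cores_per_sample = 1, n_cd8_per_core = 2,
                        n_frc_per_core = 1, n_fibers_per_core = 1,
                        censor_fraction = 1, seed = 3)
  expect_true(all(generate_cohort(cfg1)$clinical$event == 0L))

  expect_identical(generate_cohort(cfg)$cells, co$cells)
  expect_error(cohort_config(archetype_library = list()),
               class = "tilfrc_parameter_error")
})

test_that("exponential survival draws have the closed-form mean", {
  lib <- list(TFE1 = tfe_archetype("TFE1",
    stats::setNames(rep(0.25, 4), c("nonactivated", "progenitor_exhausted",
                                    "cytotoxic", "terminally_exhausted")),
    frc_ligand_level = 0.5, hazard_rate = 0.1))
  cfg <- cohort_config(n_samples = 10000, cores_per_sample = 1,
                       n_cd8_per_core = 1, n_frc_per_core = 1,
                       n_fibers_per_core = 1, censor_fraction = 0,
                       seed = 12, archetype_library = lib)
  co <- generate_cohort(cfg)
  expect_equal(mean(co$clinical$os_time), 10, tolerance = 0.03)
})

test_that("planted archetype frequencies match weights within binomial error", {
  cfg <- cohort_config(n_samples = 1, cores_per_sample = 1,
                       n_cd8_per_core = 2000, n_frc_per_core = 1,
                       n_fibers_per_core = 1, mixing_noise_sd = 0, seed = 21)
  co <- generate_cohort(cfg)
  w <- default_tfe_archetypes()$TFE1$cd8_cluster_weights
  freq <- table(factor(co$cells$archetype, levels = names(w))) / 2000
  for (a in names(w)) {
    tol <- 3 * sqrt(w[[a]] * (1 - w[[a]]) / 2000)
    expect_lt(abs(freq[[a]] - w[[a]]), tol)
  }
})

test_that("median survival ordering follows the hazard ordering across seeds", {
  ok <- vapply(1:20, function(sd) {
    cfg <- cohort_config(n_samples = 400, cores_per_sample = 1,
                         n_cd8_per_core = 1, n_frc_per_core = 1,
                         n_fibers_per_core = 1, censor_fraction = 0, seed = sd)
    clin <- generate_cohort(cfg)$clinical
    med <- tapply(clin$os_time, clin$tfe_true, stats::median)
    med[["TFE1"]] < min(med[["TFE2"]], med[["TFE3"]]) &&
      max(med[["TFE2"]], med[["TFE3"]]) < med[["TFE4"]]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("archetype constructors validate their invariants", {
  w <- stats::setNames(c(0.3, 0.3, 0.2, 0.2),
                       c("nonactivated", "progenitor_exhausted", "cytotoxic",
                         "terminally_exhausted"))
  expect_error(tfe_archetype("TFE1", w * 2, frc_ligand_level = 0.5),
               class = "tilfrc_parameter_error")
  expect_error(tfe_archetype("TFE1", w, frc_ligand_level = 0.5,
                             placement_mode = "uncoupled", clearance_um = 0),
               class = "tilfrc_parameter_error")
  means <- stats::setNames(rep(1, 5), c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2"))
  expect_error(phenotype_archetype("cytotoxic", means, means),
               class = "tilfrc_parameter_error")
})

test_that("write_cohort emits readable CSV tables", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_samples = 2, cores_per_sample = 1,
                                      n_cd8_per_core = 10, n_frc_per_core = 4,
                                      n_fibers_per_core = 4, seed = 2))
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir, c("cells.csv", "frc_cells.csv",
                                               "fibers.csv", "clinical.csv")))))
  clin <- read_clinical(file.path(dir, "clinical.csv"))
  expect_identical(nrow(clin), 2L)
})
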