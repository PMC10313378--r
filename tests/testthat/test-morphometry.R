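test_that("skeleton of a bar is one branch of near-full length", {
  g <- skeletonize_network(make_bar(), pixel_size_um = 1, prune_spur_um = 3)
  bs <- branch_statistics(g)
  expect_identical(bs$n_junctions, 0L)
  expect_identical(bs$n_branches, 1L)
  expect_gte(bs$mean_branch_length_um, 95)
  expect_lte(bs$mean_branch_length_um, 99)
})

test_that("skeleton of a plus sign has one junction and four branches", {
  bs <- branch_statistics(skeletonize_network(make_plus(), 1, 3))
  expect_identical(bs$n_junctions, 1L)
  expect_identical(bs$n_branches, 4L)
})

test_that("empty raster gives an empty graph with flagged undefined mean", {
  bs <- branch_statistics(skeletonize_network(matrix(0L, 40, 40)))
  expect_identical(bs$n_branches, 0L)
  expect_identical(bs$n_junctions, 0L)
  expect_true(is.na(bs$mean_branch_length_um))
})

test_that("skeletonization is idempotent", {
  for (m in list(make_bar(), make_plus(),
                 generate_frc_network(network_params(c(128, 128), seed = 2))$raster)) {
    sk <- thin_skeleton(m)
    expect_identical(thin_skeleton(sk), sk)
  }
})

test_that("branch count and gap radii survive a 90-degree rotation", {
  net <- generate_frc_network(network_params(c(160, 160), seed = 13))
  rot <- t(net$raster)[ncol(net$raster):1, ]
  bs1 <- branch_statistics(skeletonize_network(net$raster, 1, 3))
  bs2 <- branch_statistics(skeletonize_network(rot, 1, 3))
  expect_lte(abs(bs1$n_branches - bs2$n_branches),
             max(2, 0.05 * bs1$n_branches))
  g1 <- gap_analysis(net$raster, 1, 5, 20)
  g2 <- gap_analysis(rot, 1, 5, 20)
  expect_equal(g1$radius_um, g2$radius_um, tolerance = 0.1)
})

test_that("gap analysis inscribes the empty field's largest circle at centre", {
  gs <- gap_analysis(matrix(0L, 100, 100), 1, 5, 3)
  expect_equal(gs$radius_um[1], 50, tolerance = 1)
  expect_equal(gs$center_row[1], 50, tolerance = 2)
  expect_equal(gs$center_col[1], 50, tolerance = 2)
})

test_that("a single vertical fibre splits the field into ~25 um gaps per side", {
  vf <- matrix(0L, 100, 100); vf[, 50] <- 1L
  gs <- gap_analysis(vf, 1, 5, 10)
  # brute-force oracle: max over exact point-to-obstacle distances per side
  expect_true(all(abs(gs$radius_um[1:4] - 25) <= 1))
  sides <- sign(gs$center_col[1:4] - 50)
  expect_setequal(sides, c(-1, 1))
})

test_that("every gap circle interior is foreground-free and radii non-increasing", {
  net <- generate_frc_network(network_params(c(200, 200), seed = 17))
  gs <- gap_analysis(net$raster, 1, 5, 40)
  expect_true(all(diff(gs$radius_um) <= 1e-9))
  idx <- which(net$raster == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(gs))) {
    d2 <- (idx[, 1] - gs$center_row[i])^2 + (idx[, 2] - gs$center_col[i])^2
    expect_gte(min(sqrt(d2)), gs$radius_um[i] - 1e-6)
  }
  # all-foreground raster yields an empty set
  expect_identical(nrow(gap_analysis(matrix(1L, 30, 30), 1, 5)), 0L)
})

test_that("sparser networks have larger gaps; less branching, fewer junctions", {
  dens <- c(8, 6, 4, 2.5, 1.5)
  med <- vapply(dens, function(dn) {
    mean(vapply(c(31, 32, 35), function(sd) {
      net <- generate_frc_network(network_params(c(320, 320),
                                                 fiber_density = dn, seed = sd))
      attr(gap_analysis(net$raster, 1, 4, 10), "summary")$median_radius_um
    }, numeric(1)))
  }, numeric(1))
  expect_lte(stats::cor(dens, med, method = "spearman"), -0.9)

  probs <- c(0.01, 0.02, 0.04, 0.06, 0.08)
  juncs <- vapply(probs, function(pb) {
    mean(vapply(c(33, 34), function(sd) {
      net <- generate_frc_network(network_params(c(320, 320),
                                                 branch_prob = pb, seed = sd))
      net$truth$n_junctions
    }, numeric(1)))
  }, numeric(1))
  expect_gte(stats::cor(probs, juncs, method = "spearman"), 0.9)
})

test_that("fibre shape features match moment and skeleton oracles", {
  feats_bar <- fiber_shape_features(make_bar())
  expect_identical(nrow(feats_bar), 1L)
  expect_lte(feats_bar$elongation, 0.05)
  expect_identical(feats_bar$branchpoint_count, 0L)

  feats_disk <- fiber_shape_features(make_disk())
  expect_gte(feats_disk$elongation, 0.95)
  expect_identical(feats_disk$branchpoint_count, 0L)

  feats_plus <- fiber_shape_features(make_plus())
  expect_identical(feats_plus$branchpoint_count, 1L)
  expect_identical(feats_plus$endpoint_count, 4L)
})

test_that("planted bar and blob morphologies separate perfectly at k = 2", {
  m <- matrix(0L, 200, 200)
  bars <- matrix(FALSE, 200, 200)
  withr::with_seed(40, {
    placed <- 0
    while (placed < 6) {  # thin bars, guarded against touching
      r <- sample(5:193, 1); c0 <- sample(5:140, 1)
      gr <- max(1, r - 3):min(200, r + 4); gc <- max(1, c0 - 3):min(200, c0 + 53)
      if (all(m[gr, gc] == 0L)) {
        m[r:(r + 1), c0:(c0 + 50)] <- 1L
        bars[r:(r + 1), c0:(c0 + 50)] <- TRUE
        placed <- placed + 1
      }
    }
  })
  withr::with_seed(41, {
    placed <- 0
    while (placed < 6) {  # compact blobs
      r <- sample(15:185, 1); c0 <- sample(15:185, 1)
      guard <- tilfrc:::disc_pixels(r, c0, 9, 200, 200)
      if (all(m[guard] == 0L)) {
        m[tilfrc:::disc_pixels(r, c0, 6, 200, 200)] <- 1L
        placed <- placed + 1
      }
    }
  })
  lab <- EBImage::bwlabel(m)
  feats <- fiber_shape_features(m)
  truth <- vapply(feats$component, function(j) {
    if (any(bars[lab == j])) 1L else 2L
  }, integer(1))
  out <- classify_fiber_shapes(feats, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(out$shape_cluster, truth), 1)
  # elongated class gets the first label
  expect_true(all(out$shape_cluster[out$elongation < 0.3] == "c15"))
})

test_that("shape clustering is deterministic and falls back below k components", {
  feats <- tibble::tibble(elongation = c(0.1, 0.5, 0.9),
                          branchpoint_count = c(0L, 1L, 2L))
  expect_warning(out <- classify_fiber_shapes(feats, k = 4, seed = 1),
                 "quantile")
  expect_identical(length(unique(out$shape_cluster)), 3L)
  feats2 <- dplyr::bind_rows(feats, feats, feats, feats) |>
    dplyr::mutate(elongation = .data$elongation + seq(0, 0.05, length.out = 12))
  a <- classify_fiber_shapes(feats2, k = 4, seed = 5)
  b <- classify_fiber_shapes(feats2, k = 4, seed = 5)
  expect_identical(a$shape_cluster, b$shape_cluster)
})
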