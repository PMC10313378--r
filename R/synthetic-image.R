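#' Default IMC marker panel for synthetic cores
#'
#' Stromal markers (PDPN, CD31, FAP), tumour B cells (CD20), the CD8 lineage
#' channel, and the six phenotyping markers.
#'
#' @param pixel_size_um pixel size in micrometres.
#' @return a [marker_panel()].
#' @export
default_panel <- function(pixel_size_um = 1) {
  marker_panel(c("PDPN", "CD31", "CD20", "CD8", "FAP",
                 "PD-1", "PD-L1", "PD-L2", "LAG-3", "TIM-3", "GrB"),
               pixel_size_um = pixel_size_um)
}

# lognormal background noise floor for a channel
bg_noise <- function(nr, nc, level = 0.2) {
  matrix(stats::rlnorm(nr * nc, log(level), 0.4), nr, nc)
}

# paint a set of pixels with per-pixel lognormal jitter around `level`
paint <- function(channel, pix, level, sdlog = 0.15) {
  channel[pix] <- stats::rlnorm(length(pix), log(level), sdlog)
  channel
}

disc_pixels <- function(r0, c0, radius, nr, nc) {
  rr <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  cbind(g$r[keep], g$c[keep])
}

#' Generate one synthetic IMC core with ground truth
#'
#' Renders a multichannel image of an FRC network plus LEC/BEC blobs and CD8
#' cells drawn from a [tfe_archetype()]: PDPN is bright on network and LEC
#' pixels, CD31 on LEC/BEC blobs, FAP on a subset of FRC fibres, CD8 on cell
#' footprints, and the six phenotyping channels carry per-cell archetype
#' intensities. In `uncoupled` placement every CD8 centroid is at least
#' `clearance_um` from the nearest network pixel; in `coupled` placement 70%
#' of cells are seeded on the network with ~2 um jitter.
#'
#' @param network a [network_params()] (its `field_size_px`/`pixel_size_um`
#'   set the core geometry).
#' @param tfe a [tfe_archetype()].
#' @param n_cd8 number of CD8 cells to place (>= 0).
#' @param seed integer seed; fully determines the output.
#' @param archetype_library CD8 intensity archetypes
#'   (default [default_phenotype_archetypes()]).
#' @param sample_id,core_id identifiers.
#' @param n_lec,n_bec endothelial blob counts.
#' @param cell_radius_px CD8 footprint radius in pixels.
#' @return list with `image` ([multiplex_image()]), `truth_cells` (tibble:
#'   `cell_id`, centroid `row`/`col`, `archetype`, true marker means),
#'   `truth_map` (`stroma_map` ground truth), `label_mask` (integer matrix),
#'   `frc_mask` (0/1 matrix), `network_truth` (generator graph morphometry).
#' @export
generate_sample_image <- function(network, tfe, n_cd8 = 150, seed = 1L,
                                  archetype_library = default_phenotype_archetypes(),
                                  sample_id = "s1", core_id = "c1",
                                  n_lec = 3L, n_bec = 4L, cell_radius_px = 3L) {
  stopifnot(inherits(network, "network_params"), inherits(tfe, "tfe_archetype"))
  if (n_cd8 < 0) stop_param("n_cd8 must be >= 0")
  withr::with_seed(seed, generate_sample_image_impl(
    network, tfe, n_cd8, archetype_library, sample_id, core_id,
    n_lec, n_bec, cell_radius_px))
}

generate_sample_image_impl <- function(network, tfe, n_cd8, archetype_library,
                                       sample_id, core_id, n_lec, n_bec,
                                       cell_radius_px) {
  net <- generate_frc_network_impl(network)
  nr <- network$field_size_px[1]; nc <- network$field_size_px[2]
  px <- network$pixel_size_um
  frc_px <- net$raster == 1L

  blob <- function(n) {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(n)) {
      ctr <- c(stats::runif(1, 10, nr - 10), stats::runif(1, 10, nc - 10))
      m[disc_pixels(ctr[1], ctr[2], stats::runif(1, 5, 10), nr, nc)] <- TRUE
    }
    m
  }
  lec_px <- blob(n_lec)
  bec_px <- blob(n_bec)

  # ground-truth stroma classes from the binary layout, mirroring the gating
  # logic: PDPN+ = network or LEC; CD31+ = LEC or BEC
  pdpn_pos <- frc_px | lec_px
  cd31_pos <- lec_px | bec_px
  class_raster <- matrix(0L, nr, nc)
  class_raster[pdpn_pos & !cd31_pos] <- 1L
  class_raster[pdpn_pos & cd31_pos] <- 2L
  class_raster[!pdpn_pos & cd31_pos] <- 3L
  truth_map <- new_stroma_map(class_raster, thresholds = NULL, pixel_size_um = px)

  panel <- default_panel(px)
  ch <- lapply(panel$marker, function(m) bg_noise(nr, nc))
  names(ch) <- panel$marker
  ch$PDPN <- paint(ch$PDPN, which(pdpn_pos), 10)
  ch$CD31 <- paint(ch$CD31, which(cd31_pos), 10)
  ch$CD20 <- paint(ch$CD20, sample(which(class_raster == 0L),
                                   round(0.3 * sum(class_raster == 0L))), 3)
  # FAP marks an activated subset of FRC fibres: whole components positive
  if (any(frc_px)) {
    lab <- EBImage::bwlabel(frc_px)
    pos_comp <- which(stats::runif(max(lab)) < 0.6)
    ch$FAP <- paint(ch$FAP, which(lab %in% pos_comp & frc_px), 8)
  }
  # FRC PD-1 ligand expression: component-level positivity at the archetype's
  # ligand propensity (painted under any CD8-cell signal added later)
  if (any(frc_px)) {
    lab <- EBImage::bwlabel(frc_px)
    for (lig in c("PD-L1", "PD-L2")) {
      pos_comp <- which(stats::runif(max(lab)) < tfe$frc_ligand_level)
      if (length(pos_comp))
        ch[[lig]] <- paint(ch[[lig]], which(lab %in% pos_comp & frc_px), 8)
    }
  }

  # ---- CD8 cell placement ----
  label_mask <- matrix(0L, nr, nc)
  truth_cells <- tibble(cell_id = integer(), sample_id = character(),
                        core_id = character(), row = numeric(), col = numeric(),
                        archetype = character())
  if (n_cd8 > 0) {
    edt_px <- if (any(frc_px)) EBImage::distmap(1 - frc_px) else
      matrix(Inf, nr, nc)
    clearance_px <- tfe$clearance_um / px
    centres <- matrix(NA_real_, n_cd8, 2)
    min_sep2 <- (2 * cell_radius_px + 1)^2
    net_idx <- which(frc_px, arr.ind = TRUE)
    for (i in seq_len(n_cd8)) {
      placed <- FALSE
      for (try in seq_len(400L)) {
        if (tfe$placement_mode == "uncoupled") {
          cand <- c(stats::runif(1, cell_radius_px + 1, nr - cell_radius_px),
                    stats::runif(1, cell_radius_px + 1, nc - cell_radius_px))
          if (edt_px[round(cand[1]), round(cand[2])] < clearance_px) next
        } else if (nrow(net_idx) && stats::runif(1) < 0.7) {
          j <- sample.int(nrow(net_idx), 1)
          cand <- net_idx[j, ] + stats::rnorm(2, 0, 2 / px)
          cand[1] <- min(max(cand[1], cell_radius_px + 1), nr - cell_radius_px)
          cand[2] <- min(max(cand[2], cell_radius_px + 1), nc - cell_radius_px)
        } else {
          cand <- c(stats::runif(1, cell_radius_px + 1, nr - cell_radius_px),
                    stats::runif(1, cell_radius_px + 1, nc - cell_radius_px))
        }
        prev <- centres[seq_len(i - 1L), , drop = FALSE]
        if (nrow(prev) &&
            any((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 < min_sep2))
          next
        centres[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        stop_placement(sprintf(
          "could not place cell %d of %d after bounded retries (mode=%s, clearance=%g um)",
          i, n_cd8, tfe$placement_mode, tfe$clearance_um))
    }
    archetypes <- sample(phenotype_names, n_cd8, replace = TRUE,
                         prob = tfe$cd8_cluster_weights)
    intens <- draw_cell_intensities(archetypes, archetype_library)
    for (i in seq_len(n_cd8)) {
      pix <- disc_pixels(centres[i, 1], centres[i, 2], cell_radius_px, nr, nc)
      pix <- pix[label_mask[pix] == 0L, , drop = FALSE]
      label_mask[pix] <- i
      idx <- pix[, 1] + (pix[, 2] - 1L) * nr
      ch$CD8 <- paint(ch$CD8, idx, 12)
      for (mk in cd8_markers) ch[[mk]] <- paint(ch[[mk]], idx, intens[i, mk], 0.1)
    }
    truth_cells <- tibble(cell_id = seq_len(n_cd8), sample_id = sample_id,
                          core_id = core_id, row = centres[, 1],
                          col = centres[, 2], archetype = archetypes) |>
      dplyr::bind_cols(as_tibble(intens))
  }

  img <- multiplex_image(ch, panel, sample_id, core_id)
  list(image = img, truth_cells = truth_cells, truth_map = truth_map,
       label_mask = label_mask, frc_mask = matrix(as.integer(frc_px), nr, nc),
       network_truth = net$truth, tfe_name = tfe$name)
}
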