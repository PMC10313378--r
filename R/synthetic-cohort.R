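#' Cohort generator configuration
#'
#' A synthetic TMA-like cohort: `n_samples` patients, `cores_per_sample`
#' independent core draws per biopsy, each patient assigned a TFE archetype
#' round-robin. Per-sample archetype weights receive Gaussian jitter
#' (`mixing_noise_sd`, renormalized) shared by that patient's cores.
#' Survival times are exponential with the archetype hazard, censored
#' uniformly with probability `censor_fraction`.
#'
#' @param n_samples number of patients (> 0).
#' @param cores_per_sample cores per biopsy (default 2, the TMA convention).
#' @param n_cd8_per_core,n_frc_per_core,n_fibers_per_core objects drawn per
#'   core at `level = "cells"`.
#' @param mixing_noise_sd sd of the jitter applied to archetype weights.
#' @param censor_fraction probability a patient is censored, in \[0,1\].
#' @param level `"cells"` draws per-cell/per-fibre tables directly;
#'   `"images"` renders a full multichannel core per sample via
#'   [generate_sample_image()].
#' @param image_px image side length at `level = "images"`.
#' @param seed integer; fully determines all outputs.
#' @param archetype_library named list of [tfe_archetype()]s (non-empty).
#' @param phenotype_library named list of [phenotype_archetype()]s.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 50L, cores_per_sample = 2L,
                          n_cd8_per_core = 150L, n_frc_per_core = 120L,
                          n_fibers_per_core = 60L, mixing_noise_sd = 0.05,
                          censor_fraction = 0.2,
                          level = c("cells", "images"), image_px = 256L,
                          seed = 1L,
                          archetype_library = default_tfe_archetypes(),
                          phenotype_library = default_phenotype_archetypes()) {
  level <- match.arg(level)
  check_number(n_samples, "n_samples", 1)
  check_number(cores_per_sample, "cores_per_sample", 1)
  check_number(mixing_noise_sd, "mixing_noise_sd", 0)
  if (censor_fraction < 0 || censor_fraction > 1)
    stop_param("censor_fraction must be in [0,1]")
  if (!length(archetype_library))
    stop_param("archetype_library must be non-empty")
  structure(list(n_samples = as.integer(n_samples),
                 cores_per_sample = as.integer(cores_per_sample),
                 n_cd8_per_core = as.integer(n_cd8_per_core),
                 n_frc_per_core = as.integer(n_frc_per_core),
                 n_fibers_per_core = as.integer(n_fibers_per_core),
                 mixing_noise_sd = mixing_noise_sd,
                 censor_fraction = censor_fraction, level = level,
                 image_px = as.integer(image_px), seed = as.integer(seed),
                 archetype_library = archetype_library,
                 phenotype_library = phenotype_library),
            class = "cohort_config")
}

#' Generate a synthetic patient cohort
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle` list: `cells` (tibble of CD8 cells with raw
#'   phenotyping intensities and planted `archetype`), `frc_cells` (tibble
#'   with PD-L1/PD-L2 values per FRC object), `fibers` (tibble of fibre
#'   shape features), `clinical` (tibble: `sample_id`, `os_time` months,
#'   `event`, planted `tfe_true`), `samples` (per-core index), and at
#'   `level = "images"` also `images` (list of [generate_sample_image()]
#'   results, one per core).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  arch_names <- names(config$archetype_library)
  assigned <- rep(arch_names, length.out = config$n_samples)
  sample_ids <- sprintf("s%03d", seq_len(config$n_samples))

  cells <- list(); frc_cells <- list(); fibers <- list(); images <- list()
  samples <- list()
  for (i in seq_len(config$n_samples)) {
    tfe <- config$archetype_library[[assigned[i]]]
    w <- tfe$cd8_cluster_weights
    if (config$mixing_noise_sd > 0) {
      w <- pmax(w + stats::rnorm(length(w), 0, config$mixing_noise_sd), 1e-3)
      w <- w / sum(w)
    }
    for (k in seq_len(config$cores_per_sample)) {
      core_id <- sprintf("core%d", k)
      samples[[length(samples) + 1L]] <-
        tibble(sample_id = sample_ids[i], core_id = core_id,
               tfe_true = tfe$name)
      if (config$level == "cells") {
        n <- config$n_cd8_per_core
        arch <- sample(phenotype_names, n, replace = TRUE, prob = w)
        intens <- draw_cell_intensities(arch, config$phenotype_library)
        cells[[length(cells) + 1L]] <-
          tibble(cell_id = seq_len(n), sample_id = sample_ids[i],
                 core_id = core_id, row = stats::runif(n, 1, 500),
                 col = stats::runif(n, 1, 500), archetype = arch) |>
          dplyr::bind_cols(as_tibble(intens))
        frc_cells[[length(frc_cells) + 1L]] <-
          dplyr::bind_cols(
            tibble(cell_id = seq_len(config$n_frc_per_core),
                   sample_id = sample_ids[i], core_id = core_id),
            draw_frc_ligands(config$n_frc_per_core, tfe$frc_ligand_level))
        fibers[[length(fibers) + 1L]] <-
          dplyr::bind_cols(
            tibble(component = seq_len(config$n_fibers_per_core),
                   sample_id = sample_ids[i], core_id = core_id),
            draw_fiber_features(config$n_fibers_per_core, tfe$frc_shape_bias))
      } else {
        np <- network_params(field_size_px = c(config$image_px, config$image_px),
                             seed = stats::runif(1, 1, 2^30))
        sim <- generate_sample_image_impl(
          np, tfe, config$n_cd8_per_core, config$phenotype_library,
          sample_ids[i], core_id, n_lec = 3L, n_bec = 4L, cell_radius_px = 3L)
        images[[paste(sample_ids[i], core_id, sep = "_")]] <- sim
        cells[[length(cells) + 1L]] <- sim$truth_cells
      }
    }
  }
  clinical <- tibble(sample_id = sample_ids, tfe_true = assigned) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      hazard = config$archetype_library[[.data$tfe_true]]$hazard_rate) |>
    dplyr::ungroup()
  t_event <- stats::rexp(config$n_samples, clinical$hazard)
  censored <- stats::runif(config$n_samples) < config$censor_fraction
  clinical$os_time <- ifelse(censored, stats::runif(config$n_samples) * t_event,
                             t_event)
  clinical$event <- as.integer(!censored)
  clinical$hazard <- NULL

  out <- list(cells = dplyr::bind_rows(cells),
              frc_cells = if (length(frc_cells)) dplyr::bind_rows(frc_cells) else NULL,
              fibers = if (length(fibers)) dplyr::bind_rows(fibers) else NULL,
              clinical = clinical,
              samples = dplyr::bind_rows(samples),
              config = config)
  if (config$level == "images") out$images <- images
  class(out) <- "cohort_bundle"
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d samples x %d cores (%s level), %d CD8 cells\n",
              x$config$n_samples, x$config$cores_per_sample, x$config$level,
              nrow(x$cells)))
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' CSV tables (cells, FRC objects, fibres, clinical), and at image level one
#' multipage TIFF + 16-bit label mask + JSON ground-truth sidecar per core.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$cells, file.path(dir, "cells.csv"))
  if (!is.null(cohort$frc_cells))
    readr::write_csv(cohort$frc_cells, file.path(dir, "frc_cells.csv"))
  if (!is.null(cohort$fibers))
    readr::write_csv(cohort$fibers, file.path(dir, "fibers.csv"))
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  if (!is.null(cohort$images)) {
    for (nm in names(cohort$images)) {
      sim <- cohort$images[[nm]]
      write_multiplex_image(sim$image, file.path(dir, paste0(nm, ".tiff")))
      write_label_mask(sim$label_mask, file.path(dir, paste0(nm, "_mask.tiff")))
      jsonlite::write_json(
        list(tfe = sim$tfe_name, network_truth = sim$network_truth,
             n_cells = nrow(sim$truth_cells)),
        file.path(dir, paste0(nm, "_truth.json")), auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}
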