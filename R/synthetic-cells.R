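cd8_markers <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2", "GrB")
checkpoint_markers <- c("PD-1", "LAG-3", "TIM-3", "PD-L1", "PD-L2")
phenotype_names <- c("nonactivated", "progenitor_exhausted", "cytotoxic",
                     "terminally_exhausted")
tfe_names <- paste0("TFE", 1:4)

#' CD8 phenotype archetype
#'
#' An archetype is a named intensity profile over the six phenotyping
#' markers (five checkpoints + granzyme B). Cell intensities are drawn
#' log-normally: `marker_means` are the median raw intensities (arbitrary
#' counts) and `marker_sds` the standard deviations on the log scale, so
#' draws are positive and right-skewed as ion-count data are.
#'
#' @param name one of `nonactivated`, `progenitor_exhausted`, `cytotoxic`,
#'   `terminally_exhausted`.
#' @param marker_means,marker_sds named numeric vectors over exactly the six
#'   phenotyping markers; all values positive.
#' @return a `phenotype_archetype` list.
#' @export
phenotype_archetype <- function(name, marker_means, marker_sds) {
  name <- match.arg(name, phenotype_names)
  if (!setequal(names(marker_means), cd8_markers) ||
      !setequal(names(marker_sds), cd8_markers))
    stop_param(sprintf("marker_means/marker_sds must cover exactly: %s",
                       paste(cd8_markers, collapse = ", ")))
  if (any(marker_means <= 0) || any(marker_sds <= 0))
    stop_param("marker means and sds must be positive")
  structure(list(name = name, marker_means = marker_means[cd8_markers],
                 marker_sds = marker_sds[cd8_markers]),
            class = "phenotype_archetype")
}

#' Default CD8 archetype intensity table
#'
#' Documented fixture constants mirroring the qualitative lo/hi pattern of
#' the four phenotype identities: nonactivated = all markers low; progenitor
#' exhausted = checkpoints high, GrB low; cytotoxic = GrB high, checkpoints
#' low; terminally exhausted = all high. The numeric values are generator
#' constants, not measured values.
#'
#' @return named list of four [phenotype_archetype()]s.
#' @export
default_phenotype_archetypes <- function() {
  lo <- 2; hi <- 30
  sds <- stats::setNames(rep(0.35, 6), cd8_markers)
  mk <- function(name, ck, grb) {
    means <- stats::setNames(c(rep(ck, 5), grb), cd8_markers)
    phenotype_archetype(name, means, sds)
  }
  list(nonactivated = mk("nonactivated", lo, lo),
       progenitor_exhausted = mk("progenitor_exhausted", hi, 3),
       cytotoxic = mk("cytotoxic", 3, hi + 5),
       terminally_exhausted = mk("terminally_exhausted", hi + 5, hi + 5))
}

#' TIL-FRC environment archetype
#'
#' Defines the composition and spatial regime of one synthetic environment
#' class: the mixing weights over CD8 phenotype archetypes, the propensity
#' of FRCs to express PD-1 ligands, the fibre shape bias, whether CD8 cells
#' are placed coupled to the network or held off it, and the exponential
#' survival hazard of patients drawn from this environment.
#'
#' @param name one of TFE1..TFE4.
#' @param cd8_cluster_weights simplex over the four phenotype archetypes
#'   (named, sums to 1).
#' @param frc_ligand_level probability in \[0,1\] that an FRC is PD-L1+
#'   (independently PD-L2+).
#' @param frc_shape_bias `"elongated"` or `"circular"`.
#' @param placement_mode `"coupled"` or `"uncoupled"`.
#' @param clearance_um minimum CD8-to-network distance enforced in uncoupled
#'   mode (must be > 0 there).
#' @param hazard_rate exponential hazard of overall survival, events/month.
#' @return a `tfe_archetype` list.
#' @export
tfe_archetype <- function(name, cd8_cluster_weights, frc_ligand_level,
                          frc_shape_bias = c("elongated", "circular"),
                          placement_mode = c("coupled", "uncoupled"),
                          clearance_um = 0, hazard_rate = 0.03) {
  name <- match.arg(name, tfe_names)
  frc_shape_bias <- match.arg(frc_shape_bias)
  placement_mode <- match.arg(placement_mode)
  if (!setequal(names(cd8_cluster_weights), phenotype_names))
    stop_param("cd8_cluster_weights must be named over the four phenotype archetypes")
  w <- cd8_cluster_weights[phenotype_names]
  if (abs(sum(w) - 1) > 1e-9) stop_param("cd8_cluster_weights must sum to 1")
  if (frc_ligand_level < 0 || frc_ligand_level > 1)
    stop_param("frc_ligand_level must be in [0,1]")
  if (placement_mode == "uncoupled" && clearance_um <= 0)
    stop_param("uncoupled placement requires clearance_um > 0")
  check_number(hazard_rate, "hazard_rate", 0, strict = TRUE)
  structure(list(name = name, cd8_cluster_weights = w,
                 frc_ligand_level = frc_ligand_level,
                 frc_shape_bias = frc_shape_bias,
                 placement_mode = placement_mode,
                 clearance_um = clearance_um, hazard_rate = hazard_rate),
            class = "tfe_archetype")
}

#' Default TFE archetype library
#'
#' Four environments following the qualitative composition and survival
#' ordering of the TFE descriptions: TFE1 exhausted-enriched, spatially
#' uncoupled (12 um clearance) and worst survival; TFE2 progenitor-exhausted
#' and ligand-high; TFE3 nonactivated with circular, ligand-low FRCs; TFE4
#' cytotoxic-enriched with best survival. Hazards give a TFE1:TFE4 ratio of
#' 4 with TFE2/TFE3 intermediate. Weights and hazards are generator
#' constants, not measured values.
#'
#' @return named list of four [tfe_archetype()]s.
#' @export
default_tfe_archetypes <- function() {
  w <- function(non, prog, cyto, term)
    stats::setNames(c(non, prog, cyto, term), phenotype_names)
  list(
    TFE1 = tfe_archetype("TFE1", w(0.10, 0.40, 0.10, 0.40),
                         frc_ligand_level = 0.5, frc_shape_bias = "elongated",
                         placement_mode = "uncoupled", clearance_um = 12,
                         hazard_rate = 0.060),
    TFE2 = tfe_archetype("TFE2", w(0.25, 0.50, 0.10, 0.15),
                         frc_ligand_level = 0.8, frc_shape_bias = "elongated",
                         placement_mode = "coupled", hazard_rate = 0.035),
    TFE3 = tfe_archetype("TFE3", w(0.55, 0.15, 0.20, 0.10),
                         frc_ligand_level = 0.1, frc_shape_bias = "circular",
                         placement_mode = "coupled", hazard_rate = 0.025),
    TFE4 = tfe_archetype("TFE4", w(0.20, 0.10, 0.60, 0.10),
                         frc_ligand_level = 0.4, frc_shape_bias = "elongated",
                         placement_mode = "coupled", hazard_rate = 0.015))
}

# draw per-cell raw marker intensities for given archetype names
draw_cell_intensities <- function(archetype_names, library) {
  out <- matrix(0, length(archetype_names), length(cd8_markers),
                dimnames = list(NULL, cd8_markers))
  for (an in unique(archetype_names)) {
    arch <- library[[an]]
    sel <- which(archetype_names == an)
    for (mk in cd8_markers) {
      out[sel, mk] <- stats::rlnorm(length(sel),
                                    meanlog = log(arch$marker_means[[mk]]),
                                    sdlog = arch$marker_sds[[mk]])
    }
  }
  out
}

# draw per-FRC ligand intensities: positive cells bright, negative cells dim
draw_frc_ligands <- function(n, ligand_level) {
  draw1 <- function() {
    pos <- stats::runif(n) < ligand_level
    ifelse(pos, stats::rlnorm(n, log(8), 0.3), stats::rlnorm(n, log(0.5), 0.3))
  }
  tibble(`PD-L1` = draw1(), `PD-L2` = draw1())
}

# draw fibre shape feature rows reflecting the archetype bias
draw_fiber_features <- function(n, shape_bias) {
  if (shape_bias == "elongated") {
    elong <- stats::rbeta(n, 2, 6)
    bp <- stats::rpois(n, 1.2)
  } else {
    elong <- stats::rbeta(n, 6, 2)
    bp <- stats::rpois(n, 3)
  }
  tibble(elongation = pmin(pmax(elong, 1e-3), 1), branchpoint_count = bp,
         area_um2 = stats::rlnorm(n, log(80), 0.5))
}
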