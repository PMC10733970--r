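## Species cell presets: reduced morphology + channel library + default
## conductance densities. These are the ground-truth generators for the
## synthetic studies and the baseline cells for the synaptic-drive
## experiments.

#' Default per-region peak conductances (S/cm2)
#'
#' Uniformly distributed channels get one density per region; KAd, KD and Ih
#' are graded with distance and handled by [default_distribution_rules()].
#'
#' @param species `"mouse"` or `"rat"`.
#' @return Named list `channel -> region -> density`.
#' @export
default_region_gbars <- function(species = c("mouse", "rat")) {
  species <- match.arg(species)
  dend_na <- 0.022
  g <- list(
    Na3 = list(soma = 0.032, basal = dend_na, apical_trunk = dend_na,
               oblique = dend_na),
    Nax = list(axon = 0.064),
    KDR = list(soma = 0.006, axon = 0.01, basal = 0.004,
               apical_trunk = 0.004, oblique = 0.004),
    KAp = list(soma = 0.015, axon = 0.03, basal = 0.012),
    KM  = list(soma = 5e-4, axon = 5e-4),
    CaN = list(soma = 5e-4, basal = 2e-4, apical_trunk = 2e-4,
               oblique = 2e-4),
    CaL = list(soma = 2e-4, apical_trunk = 1e-4),
    CaT = list(soma = 2e-4, basal = 2e-4, apical_trunk = 2e-4,
               oblique = 2e-4),
    KCa = list(soma = 5e-4, basal = 2.5e-4, apical_trunk = 2.5e-4,
               oblique = 2.5e-4),
    Cagk = list(soma = 4e-3, basal = 2e-4, apical_trunk = 2e-4,
                oblique = 2e-4))
  g
}

#' Default distance-dependent distribution rules
#'
#' Ih and the distal A-type current increase linearly ~6-fold over 350 um;
#' KD follows a sigmoidal distal ramp (conventions of the rat CA1 model
#' family). All editable.
#'
#' @param gbar_ih_base Somatic/proximal Ih density (S/cm2).
#' @param gbar_kad_base Proximal KAd density (S/cm2).
#' @param gbar_kd_base KD sigmoid base density (S/cm2).
#' @return List of [distribution_rule()] objects.
#' @export
default_distribution_rules <- function(gbar_ih_base = 1e-5,
                                       gbar_kad_base = 0.012,
                                       gbar_kd_base = 5e-4) {
  dend <- c("basal", "apical_trunk", "oblique")
  list(
    distribution_rule("Ih", dend, "linear_with_distance",
                      base = gbar_ih_base,
                      slope = 5 * gbar_ih_base / 350),
    distribution_rule("KAd", c("apical_trunk", "oblique"),
                      "linear_with_distance", base = gbar_kad_base,
                      slope = 5 * gbar_kad_base / 350),
    distribution_rule("KD", c("apical_trunk", "oblique"),
                      "sigmoidal_with_distance", base = gbar_kd_base,
                      amp = 3 * gbar_kd_base, midpoint = 200,
                      steepness = 50))
}

#' Default passive properties
#' @param species `"mouse"` or `"rat"`.
#' @return List (g_pas S/cm2, e_pas mV, cm uF/cm2, Ra Ohm*cm).
#' @export
default_passive <- function(species = c("mouse", "rat")) {
  species <- match.arg(species)
  list(g_pas = if (species == "mouse") 5e-5 else 1.1e-4,
       e_pas = -65, cm = 1, Ra = 150)
}

#' Assembled species cell preset
#'
#' Reduced morphology, species channel library (with somatic Ih added via a
#' region density so the soma also carries the graded channels' base
#' density), default densities and passive properties.
#'
#' @param species `"mouse"` or `"rat"`.
#' @param region_gbars Override for [default_region_gbars()].
#' @param rules Override for [default_distribution_rules()].
#' @param passive Override for [default_passive()].
#' @param max_seg_um Spatial discretization bound (um).
#' @return A `cable_cell` with attribute `"species"`.
#' @export
cell_preset <- function(species = c("mouse", "rat"), region_gbars = NULL,
                        rules = NULL, passive = NULL, max_seg_um = 20) {
  species <- match.arg(species)
  morph <- build_reduced_morphology(species)
  comps <- discretize(morph, max_seg_um)
  lib <- default_channel_library(species)
  if (is.null(region_gbars)) region_gbars <- default_region_gbars(species)
  if (is.null(rules)) rules <- default_distribution_rules()
  if (is.null(passive)) passive <- default_passive(species)
  ## soma carries the graded channels at their base density
  region_gbars$Ih <- utils::modifyList(
    list(soma = rules[[1]]$base), as.list(region_gbars$Ih))
  dens <- apply_distributions(comps, rules, region_gbars)
  cell <- assemble(comps, dens, lib, passive = passive)
  attr(cell, "species") <- species
  cell
}
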