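#' Per-cell carbon and nitrogen contents
#'
#' Reference elemental contents (pmol cell-1) per host cell type. Akinetes
#' are nutrient-storing cells roughly ten times the biomass of a vegetative
#' cell, so their default contents are 10x the vegetative values; heterocytes
#' default to vegetative-like contents. The vegetative carbon content is
#' calibrated so that the population-mean vegetative carbon incorporation
#' rate of 0.39 pmol C cell-1 d-1 arises at the default mean vegetative 13C
#' enrichment; all entries are plain config values and can be replaced.
#'
#' @param vegetative,heterocyte,akinete Numeric length-2 vectors
#'   \code{c(C = , N = )} in pmol cell-1.
#' @return data.frame with columns \code{category}, \code{C_content},
#'   \code{N_content}, one row per ROI category that carries biomass.
#' @export
cellTypeParams <- function(vegetative = c(C = 4.0, N = 0.62),
                           heterocyte = c(C = 4.0, N = 0.62),
                           akinete    = c(C = 40,  N = 6.2)) {
  for (v in list(vegetative, heterocyte, akinete))
    if (any(v <= 0)) stop("cell contents must be positive")
  data.frame(
    category = c("vegetative", "heterocyte_I", "heterocyte_II",
                 "akinete_I", "akinete_II"),
    C_content = c(vegetative["C"], heterocyte["C"], heterocyte["C"],
                  akinete["C"], akinete["C"]),
    N_content = c(vegetative["N"], heterocyte["N"], heterocyte["N"],
                  akinete["N"], akinete["N"]),
    row.names = NULL)
}

#' Default true-enrichment table for the population simulator
#'
#' Mean and SD of true 13C and 15N atom-percent excess (APE) per simulated
#' ROI group. Sporangium and bacterium groups use the observed group means
#' for mature sporangia at akinete-heterocyte junctions, sporangia on
#' vegetative and type II host cells, host-associated and free-living
#' bacteria. Host-cell groups are derived from the infected/non-infected
#' incorporation-rate table via the linear tracer model (APE =
#' rate / content * source APE * dt) at the default labeling (3.9 at% excess
#' 13C-DIC, 0.67 at% excess 15N-N2) and 21 h (0.875 d) incubation.
#'
#' @param labeling Source-pool enrichments, \code{c(apeC = , apeN = )} in
#'   atom percent excess.
#' @param dt_days Incubation duration in days.
#' @param contents Output of [cellTypeParams()].
#' @return data.frame with columns \code{group}, \code{ape13C_mean},
#'   \code{ape13C_sd}, \code{ape15N_mean}, \code{ape15N_sd}.
#' @export
defaultEnrichment <- function(labeling = c(apeC = 3.9, apeN = 0.67),
                              dt_days = 0.875,
                              contents = cellTypeParams()) {
  # printed mean +/- SD incorporation rates (pmol cell-1 d-1)
  rate <- defaultRateTable()
  host <- do.call(rbind, lapply(seq_len(nrow(rate)), function(i) {
    r <- rate[i, ]
    cc <- contents[contents$category == r$category, ]
    data.frame(
      group = paste0(r$category, "_", r$status),
      ape13C_mean = r$r_C / cc$C_content * labeling[["apeC"]] * dt_days,
      ape13C_sd   = r$r_C_sd / cc$C_content * labeling[["apeC"]] * dt_days,
      ape15N_mean = r$r_N / cc$N_content * labeling[["apeN"]] * dt_days,
      ape15N_sd   = r$r_N_sd / cc$N_content * labeling[["apeN"]] * dt_days)
  }))
  other <- data.frame(
    group = c("sporangium_akihet", "sporangium_veg", "sporangium_het_II",
              "sporangium_aki_II", "bacterium_associated", "bacterium_free",
              "control"),
    ape13C_mean = c(1.42, 0.32, 0.35, 0.19, 0.59, 0.18, 0),
    ape13C_sd   = c(0.33, 0.33, 0.54, 0.09, 0.42, 0.11, 0),
    ape15N_mean = c(0.25, 0.02, 0.04, 0.02, 0.08, 0.043, 0),
    ape15N_sd   = c(0.10, 0.01, 0.05, 0.01, 0.07, 0.018, 0))
  rbind(host, other)
}

#' Printed per-cell incorporation-rate table
#'
#' Group means and SDs of net carbon and nitrogen incorporation rates
#' (pmol cell-1 d-1) for non-infected and fungal-infected host cells, used
#' as the default rate table of the population budget and to derive the
#' simulator's host enrichments. Type II heterocytes/akinetes default to the
#' type I values.
#'
#' @return data.frame with columns \code{category}, \code{status},
#'   \code{r_C}, \code{r_C_sd}, \code{r_N}, \code{r_N_sd}.
#' @export
defaultRateTable <- function() {
  data.frame(
    category = rep(c("vegetative", "heterocyte_I", "heterocyte_II",
                     "akinete_I", "akinete_II"), each = 2),
    status = rep(c("non_infected", "infected"), 5),
    r_C    = c(0.39, 0.38, 0.10, 0.08, 0.10, 0.08, 4.5, 3.2, 4.5, 3.2),
    r_C_sd = c(0.08, 0.10, 0.05, 0.04, 0.05, 0.04, 1.1, 1.2, 1.1, 1.2),
    r_N    = c(0.04, 0.04, 0.018, 0.013, 0.018, 0.013, 0.71, 0.31, 0.71, 0.31),
    r_N_sd = c(0.02, 0.02, 0.011, 0.010, 0.011, 0.010, 0.45, 0.21, 0.45, 0.21))
}

#' Population simulation configuration
#'
#' Describes a Dolichospermum-like bloom population: marginal cell-type
#' composition, per-type infection prevalence, filament-length distributions
#' for infected and non-infected filaments, sporangial-stage mix, bacterial
#' colonization, and the true isotopic enrichments of every ROI group.
#'
#' Akinetes are concentrated in infected filaments
#' (\code{akinete_infected_bias} is the ratio of the akinete fraction in
#' infected-class vs non-infected-class filaments), which is what allows a
#' per-type akinete prevalence above the filament-level prevalence.
#'
#' @param n_cells Number of host cells to simulate.
#' @param composition Marginal fractions \code{c(vegetative=, heterocyte=,
#'   akinete=)}; must sum to 1 within 1e-9.
#' @param prevalence_by_type Infection probability per cell type.
#' @param filament_infected_frac Fraction of filaments carrying infections.
#' @param filament_length_um List with \code{infected} and
#'   \code{non_infected} elements, each \code{c(mean=, sd=)} in um.
#' @param cell_length_um Mean cell length along the filament axis (um).
#' @param akinete_infected_bias Akinete enrichment of infected-class
#'   filaments (ratio of class-specific akinete fractions).
#' @param junction_affinity Probability that an akinete is relocated next
#'   to a heterocyte within its filament, making akinete-heterocyte
#'   junctions the dominant arrangement of differentiated cells.
#' @param sporangial_stage_probs Multinomial stage mix for sporangia.
#' @param bacteria_zinb List with \code{non_infected} and \code{infected}
#'   elements, each \code{c(pi=, mu=, k=)}: zero-inflated negative binomial
#'   parameters of per-cell bacterial colonization counts.
#' @param n_free_bacteria,n_control Numbers of free-living bacterium and
#'   non-enriched control ROIs to add.
#' @param true_enrichment Enrichment table, see [defaultEnrichment()].
#' @param cell_contents See [cellTypeParams()].
#' @param labeling Source-pool enrichment \code{c(apeC=, apeN=)} (at% excess).
#' @param dt_days Incubation duration (d).
#' @param cells_per_ml Population abundance (cells mL-1).
#' @param seed Master RNG seed.
#' @return A validated list of class \code{"PopulationConfig"}.
#' @export
populationConfig <- function(n_cells = 3000,
                             composition = c(vegetative = 0.91,
                                             heterocyte = 0.07,
                                             akinete = 0.02),
                             prevalence_by_type = c(vegetative = 0.05,
                                                    heterocyte = 0.44,
                                                    akinete = 0.82),
                             filament_infected_frac = 0.57,
                             filament_length_um = list(
                               infected = c(mean = 272, sd = 206),
                               non_infected = c(mean = 99, sd = 70)),
                             cell_length_um = 7.6,
                             akinete_infected_bias = 4.2,
                             junction_affinity = 0.85,
                             sporangial_stage_probs = c(encysted = 0.2,
                                                        mature = 0.5,
                                                        collapsed = 0.3),
                             bacteria_zinb = list(
                               non_infected = c(pi = 0.6, mu = 0.5, k = 1.0),
                               infected = c(pi = 0.6, mu = 4.25, k = 1.31)),
                             n_free_bacteria = 12,
                             n_control = 30,
                             true_enrichment = defaultEnrichment(),
                             cell_contents = cellTypeParams(),
                             labeling = c(apeC = 3.9, apeN = 0.67),
                             dt_days = 0.875,
                             cells_per_ml = 2298,
                             seed = 1L) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1 (got ", sum(composition), ")")
  if (any(prevalence_by_type < 0 | prevalence_by_type > 1))
    stop("prevalences must lie in [0, 1]")
  if (filament_infected_frac < 0 || filament_infected_frac > 1)
    stop("filament_infected_frac must lie in [0, 1]")
  for (fl in filament_length_um)
    if (fl[["mean"]] <= 0 || fl[["sd"]] < 0)
      stop("filament length mean must be > 0 and sd >= 0")
  if (any(abs(sum(sporangial_stage_probs) - 1) > 1e-9))
    stop("sporangial_stage_probs must sum to 1")
  if (any(true_enrichment$ape13C_sd < 0) || any(true_enrichment$ape15N_sd < 0))
    stop("enrichment SDs must be >= 0")
  if (labeling[["apeC"]] <= 0 || labeling[["apeN"]] <= 0)
    stop("labeling levels must be > 0")
  structure(list(
    n_cells = n_cells, composition = composition,
    prevalence_by_type = prevalence_by_type,
    filament_infected_frac = filament_infected_frac,
    filament_length_um = filament_length_um,
    cell_length_um = cell_length_um,
    akinete_infected_bias = akinete_infected_bias,
    junction_affinity = junction_affinity,
    sporangial_stage_probs = sporangial_stage_probs,
    bacteria_zinb = bacteria_zinb,
    n_free_bacteria = n_free_bacteria, n_control = n_control,
    true_enrichment = true_enrichment, cell_contents = cell_contents,
    labeling = labeling, dt_days = dt_days, cells_per_ml = cells_per_ml,
    seed = seed), class = "PopulationConfig")
}

#' SIMS acquisition simulation configuration
#'
#' Parameters of the simulated ion-count acquisition: raster geometry,
#' number of planes, expected cumulative denominator-ion counts per ROI,
#' natural-abundance baselines, and a multiplicative instrument
#' mass-fractionation factor applied to all simulated ratios.
#'
#' @param n_planes Number of acquisition planes (>= 1; acquisitions
#'   typically record at least 50 planes).
#' @param raster_px Image side length in pixels.
#' @param raster_um Physical raster size (um).
#' @param mean_counts_per_roi Expected cumulative denominator-ion counts per
#'   ROI over all planes.
#' @param natural_ratio_13C,natural_ratio_15N Non-enriched isotope-ratio
#'   baselines.
#' @param instrument_alpha Simulated mass-fractionation factor (ratios are
#'   multiplied by this before counts are drawn).
#' @param instrument \code{"large_geometry"} or \code{"nano"}.
#' @param background_frac Background pixel count rate relative to in-ROI
#'   denominator rate.
#' @param seed RNG seed used when drawing counts.
#' @return A validated list of class \code{"SimSIMSConfig"}.
#' @export
simsConfig <- function(n_planes = 50, raster_px = 128,
                       raster_um = 70,
                       mean_counts_per_roi = 1e5,
                       natural_ratio_13C = naturalRatios()[["r13C"]],
                       natural_ratio_15N = naturalRatios()[["r15N"]],
                       instrument_alpha = 0.96,
                       instrument = c("large_geometry", "nano"),
                       background_frac = 0.02,
                       seed = 1L) {
  instrument <- match.arg(instrument)
  if (n_planes < 1) stop("n_planes must be >= 1")
  if (mean_counts_per_roi <= 0) stop("mean_counts_per_roi must be > 0")
  if (natural_ratio_13C <= 0 || natural_ratio_15N <= 0)
    stop("natural ratios must be > 0")
  if (instrument_alpha <= 0) stop("instrument_alpha must be > 0")
  structure(list(
    n_planes = as.integer(n_planes), raster_px = as.integer(raster_px),
    raster_um = raster_um, mean_counts_per_roi = mean_counts_per_roi,
    natural_ratio_13C = natural_ratio_13C,
    natural_ratio_15N = natural_ratio_15N,
    instrument_alpha = instrument_alpha, instrument = instrument,
    background_frac = background_frac, seed = seed),
    class = "SimSIMSConfig")
}

# map an ROI (category, infection status, host context) to its
# true-enrichment group key
enrichmentGroup <- function(category, infection_status, host_context = NA) {
  if (category %in% .HOST_CATEGORIES) {
    status <- if (identical(infection_status, "infected")) "infected"
              else "non_infected"
    return(paste0(category, "_", status))
  }
  if (category == "sporangium") {
    return(switch(as.character(host_context),
                  vegetative = "sporangium_veg",
                  heterocyte_II = "sporangium_het_II",
                  akinete_II = "sporangium_aki_II",
                  "sporangium_akihet"))
  }
  if (category == "bacterium") {
    return(if (identical(host_context, "free_living")) "bacterium_free"
           else "bacterium_associated")
  }
  "control"
}
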