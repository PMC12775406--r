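#' Population state of a bloom snapshot
#'
#' Composition, per-type infection prevalence, and abundances of the
#' Dolichospermum population and its bacterioplankton background, as
#' observed during the tracer incubation.
#'
#' @param composition Fractions \code{c(vegetative=, heterocyte=,
#'   akinete=)}; must sum to 1.
#' @param prevalence Observed infection prevalence per cell type.
#' @param cells_per_ml,filaments_per_ml,free_bacteria_per_ml Abundances.
#' @return Validated list of class \code{"PopulationState"}.
#' @export
populationState <- function(composition = c(vegetative = 0.91,
                                            heterocyte = 0.07,
                                            akinete = 0.02),
                            prevalence = c(vegetative = 0.05,
                                           heterocyte = 0.44,
                                           akinete = 0.82),
                            cells_per_ml = 2298,
                            filaments_per_ml = 88,
                            free_bacteria_per_ml = 1.13e6) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (cells_per_ml < 0 || filaments_per_ml < 0 || free_bacteria_per_ml < 0)
    stop("abundances must be >= 0")
  structure(list(composition = composition, prevalence = prevalence,
                 cells_per_ml = cells_per_ml,
                 filaments_per_ml = filaments_per_ml,
                 free_bacteria_per_ml = free_bacteria_per_ml),
            class = "PopulationState")
}

#' Budget parameters for the epidemic extrapolation
#'
#' Per-cell incorporation rates by type and infection status, sporangium
#' and bacterial nitrogen-uptake parameters, the total newly fixed
#' nitrogen inventory, and the prevalence-scenario anchor. Sporangium and
#' bacterial uptake defaults are calibrated from the single-cell enrichment
#' measurements (content x APE / (source APE x dt)); the contents are plain
#' config entries.
#'
#' @param rate_table data.frame with columns \code{cell_type}
#'   (vegetative/heterocyte/akinete), \code{status}
#'   (non_infected/infected), \code{r_C}, \code{r_N} (pmol cell-1 d-1).
#' @param sporangia_per_infected_cell Sporangia per infected cell.
#' @param sporangium_N_content_pmol Sporangium nitrogen content (pmol N).
#' @param sporangium_ape15N Mean sporangium 15N APE used for calibration.
#' @param bacteria_N_content_pmol Bacterial cell nitrogen quota (pmol N).
#' @param bacteria_ape15N Named \code{c(associated=, free=)} mean 15N APEs.
#' @param bacteria_per_cell Named \code{c(non_infected=, infected=)} mean
#'   colonization counts per host cell.
#' @param labeling_apeN Source-pool 15N enrichment (at% excess).
#' @param dt_days Incubation duration (d).
#' @param total_new_N Total newly fixed nitrogen inventory
#'   (pmol N mL-1 d-1); the "Others" pool is the residual of this total.
#' @param scenario_anchor Per-type prevalences at the maximum total
#'   prevalence of the scan.
#' @param sporangium_N_uptake,bacteria_N_uptake Optional direct overrides
#'   (pmol N d-1 per sporangium / per bacterium c(associated=, free=)).
#' @return Validated list of class \code{"BudgetParams"}.
#' @export
budgetParams <- function(rate_table = budgetRateTable(),
                         sporangia_per_infected_cell = 1,
                         sporangium_N_content_pmol = 0.56,
                         sporangium_ape15N = 0.25,
                         bacteria_N_content_pmol = 6.1e-4,
                         bacteria_ape15N = c(associated = 0.08, free = 0.043),
                         bacteria_per_cell = c(non_infected = 0.2,
                                               infected = 1.7),
                         labeling_apeN = 0.67, dt_days = 0.875,
                         total_new_N = 230,
                         scenario_anchor = c(vegetative = 0.06,
                                             heterocyte = 0.54,
                                             akinete = 1.00),
                         sporangium_N_uptake = NULL,
                         bacteria_N_uptake = NULL) {
  if (any(scenario_anchor < 0 | scenario_anchor > 1))
    stop("scenario_anchor prevalences must lie in [0, 1]")
  if (any(rate_table$r_C < 0) || any(rate_table$r_N < 0))
    stop("rates must be >= 0")
  kfac <- 1 / (labeling_apeN * dt_days)
  if (is.null(sporangium_N_uptake))
    sporangium_N_uptake <- sporangium_N_content_pmol * sporangium_ape15N * kfac
  if (is.null(bacteria_N_uptake))
    bacteria_N_uptake <- c(
      associated = bacteria_N_content_pmol * bacteria_ape15N[["associated"]] * kfac,
      free = bacteria_N_content_pmol * bacteria_ape15N[["free"]] * kfac)
  structure(list(rate_table = rate_table,
                 sporangia_per_infected_cell = sporangia_per_infected_cell,
                 sporangium_N_uptake = sporangium_N_uptake,
                 bacteria_N_uptake = bacteria_N_uptake,
                 bacteria_per_cell = bacteria_per_cell,
                 total_new_N = total_new_N,
                 scenario_anchor = scenario_anchor),
            class = "BudgetParams")
}

#' Budget rate table from the printed type-I group means
#'
#' Collapses the per-category rate table ([defaultRateTable()]) to the
#' three cell types of the budget (vegetative, heterocyte, akinete), using
#' the type I values for differentiated cells.
#'
#' @return data.frame with \code{cell_type}, \code{status}, \code{r_C},
#'   \code{r_N}.
#' @export
budgetRateTable <- function() {
  full <- defaultRateTable()
  pick <- full[full$category %in% c("vegetative", "heterocyte_I",
                                    "akinete_I"), ]
  data.frame(cell_type = sub("_I$", "", pick$category),
             status = pick$status, r_C = pick$r_C, r_N = pick$r_N)
}

#' Observed prevalence and filament metrics from an ROISet
#'
#' Filament-level prevalence (filaments carrying at least one sporangium
#' over all filaments with at least four cells — shorter chains are not
#' counted as filaments), per-cell-type prevalences, and length summaries
#' of infected vs non-infected filaments.
#'
#' @param rois An [ROISet-class] with filament and infection annotations.
#' @param cell_length_um Cell length used to translate cell counts into
#'   filament lengths when no length column is present.
#' @return List with \code{filament_prevalence_pct},
#'   \code{cell_prevalence_pct} (per cell type),
#'   \code{total_cell_prevalence_pct}, \code{n_filaments}, and
#'   \code{filament_lengths} (data.frame: filament_id, n_cells, length_um,
#'   infected).
#' @export
computePrevalence <- function(rois, cell_length_um = 7.6) {
  info <- roiInfo(rois)
  cells <- info[info$category %in% .HOST_CATEGORIES &
                  !is.na(info$filament_id), ]
  if (nrow(cells) == 0L) stop("no filaments in ROISet")
  n_by_fil <- table(cells$filament_id)
  valid_fil <- as.integer(names(n_by_fil)[n_by_fil >= 4L])
  if (length(valid_fil) == 0L) stop("no filaments with >= 4 cells")
  cells <- cells[cells$filament_id %in% valid_fil, ]
  spor <- info[info$category == "sporangium" &
                 info$filament_id %in% valid_fil, ]
  infected_fil <- unique(spor$filament_id)
  cell_type <- ifelse(grepl("^heterocyte", cells$category), "heterocyte",
                      ifelse(grepl("^akinete", cells$category), "akinete",
                             "vegetative"))
  prev_by_type <- vapply(c("vegetative", "heterocyte", "akinete"),
                         function(t) {
    sel <- cell_type == t
    if (!any(sel)) return(NA_real_)
    100 * mean(cells$infection_status[sel] == "infected")
  }, numeric(1))
  fl <- do.call(rbind, lapply(valid_fil, function(f) {
    n <- sum(cells$filament_id == f)
    data.frame(filament_id = f, n_cells = n,
               length_um = n * cell_length_um,
               infected = f %in% infected_fil)
  }))
  list(filament_prevalence_pct = 100 * length(infected_fil) /
         length(valid_fil),
       cell_prevalence_pct = prev_by_type,
       total_cell_prevalence_pct =
         100 * mean(cells$infection_status == "infected"),
       n_filaments = length(valid_fil),
       filament_lengths = fl)
}

#' Weighted cell-level infection prevalence
#'
#' P = 100 * sum(f_type * p_type): the population-wide fraction of
#' infected cells given the composition and per-type prevalences.
#'
#' @param composition Cell-type fractions (sum to 1).
#' @param prevalence Per-type infection prevalences in [0, 1].
#' @return Total prevalence in percent (full precision; round for
#'   presentation).
#' @export
weightedPrevalence <- function(composition, prevalence) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1")
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  100 * sum(composition * prevalence)
}

#' Per-type prevalences for a total-prevalence scenario
#'
#' Scales the anchor per-type prevalences linearly so that the weighted
#' cell-level prevalence equals \code{P_total}; the anchor (default 100%
#' akinetes, 54% heterocytes, 6% vegetative cells) defines the maximum of
#' the scan.
#'
#' @param P_total Target total prevalence in percent.
#' @param params A [budgetParams()] (for the anchor).
#' @param composition Cell-type fractions.
#' @return Named per-type prevalence vector in [0, 1].
#' @export
prevalenceScenario <- function(P_total, params = budgetParams(),
                               composition = populationState()$composition) {
  anchor <- params$scenario_anchor
  P_max <- weightedPrevalence(composition, anchor)
  if (P_total < 0 || P_total > P_max + 1e-9)
    stop("P_total must lie in [0, ", round(P_max, 2), "] for this anchor")
  anchor * P_total / P_max
}

.population_cell_rate <- function(composition, prevalence, rate_table,
                                  element = c("C", "N")) {
  element <- match.arg(element)
  col <- if (element == "C") "r_C" else "r_N"
  total <- 0
  for (t in names(composition)) {
    rn <- rate_table[rate_table$cell_type == t &
                       rate_table$status == "non_infected", col]
    ri <- rate_table[rate_table$cell_type == t &
                       rate_table$status == "infected", col]
    if (length(rn) != 1L || length(ri) != 1L)
      stop("rate table lacks entries for cell type ", t)
    p <- prevalence[[t]]
    total <- total + composition[[t]] * ((1 - p) * rn + p * ri)
  }
  total
}

#' Population fixation retention across a prevalence scan
#'
#' For each total prevalence P, the population per-cell rate is the
#' composition-weighted mix of infected and non-infected rates at the
#' scenario per-type prevalences; retention is expressed relative to the
#' zero-prevalence population.
#'
#' @param state A [populationState()].
#' @param params A [budgetParams()].
#' @param P_scan Numeric vector of total prevalences (%).
#' @return data.frame with \code{P_total}, per-cell rates \code{rate_C},
#'   \code{rate_N} (pmol cell-1 d-1), \code{retained_C_pct},
#'   \code{retained_N_pct}, \code{cn_retained}.
#' @export
populationFixation <- function(state, params = budgetParams(),
                               P_scan = seq(0, 11, by = 0.5)) {
  comp <- state$composition
  r0C <- .population_cell_rate(comp, c(vegetative = 0, heterocyte = 0,
                                       akinete = 0), params$rate_table, "C")
  r0N <- .population_cell_rate(comp, c(vegetative = 0, heterocyte = 0,
                                       akinete = 0), params$rate_table, "N")
  rows <- lapply(P_scan, function(P) {
    p <- prevalenceScenario(P, params, comp)
    rC <- .population_cell_rate(comp, p, params$rate_table, "C")
    rN <- .population_cell_rate(comp, p, params$rate_table, "N")
    data.frame(P_total = P, rate_C = rC, rate_N = rN,
               retained_C_pct = 100 * rC / r0C,
               retained_N_pct = 100 * rN / r0N,
               cn_retained = rC / rN)
  })
  do.call(rbind, rows)
}

#' Retained C:N ratio at a given prevalence
#'
#' Ratio of the population-summed retained carbon to retained nitrogen at
#' total prevalence \code{P_total}; increases with prevalence when
#' infection depresses nitrogen retention more than carbon retention.
#'
#' @inheritParams populationFixation
#' @param P_total Total prevalence (%).
#' @return mol:mol ratio.
#' @export
cnRetainedRatio <- function(state, params = budgetParams(), P_total) {
  fx <- populationFixation(state, params, P_total)
  if (any(fx$rate_N <= 0)) stop("retained nitrogen is zero; ratio undefined")
  fx$cn_retained
}

#' Fate partitioning of newly fixed nitrogen
#'
#' Splits the daily inventory of newly fixed nitrogen among host retention,
#' the fungal sporangium population, host-associated and free-living
#' bacteria, and a residual "Others" pool (the remainder of the total
#' newly fixed nitrogen after the named pools). Fractions are normalized to
#' 100%.
#'
#' @inheritParams populationFixation
#' @param P_total Total prevalence (%), scalar or vector.
#' @return data.frame with one row per \code{P_total}: pool inventories
#'   (pmol N mL-1 d-1) and fate fractions (%): \code{host_retained_pct},
#'   \code{fungi_pct}, \code{bacteria_associated_pct},
#'   \code{bacteria_free_pct}, \code{others_pct}.
#' @export
nitrogenFate <- function(state, params = budgetParams(), P_total = 9.27) {
  rows <- lapply(P_total, function(P) {
    p <- prevalenceScenario(P, params, state$composition)
    host <- state$cells_per_ml *
      .population_cell_rate(state$composition, p, params$rate_table, "N")
    frac_inf <- sum(state$composition * p)
    fungi <- state$cells_per_ml * frac_inf *
      params$sporangia_per_infected_cell * params$sporangium_N_uptake
    mean_bact <- (1 - frac_inf) * params$bacteria_per_cell[["non_infected"]] +
      frac_inf * params$bacteria_per_cell[["infected"]]
    bact_assoc <- state$cells_per_ml * mean_bact *
      params$bacteria_N_uptake[["associated"]]
    bact_free <- state$free_bacteria_per_ml *
      params$bacteria_N_uptake[["free"]]
    total <- params$total_new_N
    others <- total - host - fungi - bact_assoc - bact_free
    if (others < 0)
      stop("configuration error: named pools (",
           round(host + fungi + bact_assoc + bact_free, 1),
           " pmol N mL-1 d-1) exceed total_new_N (", total, ")")
    data.frame(P_total = P,
               host_pool = host, fungi_pool = fungi,
               bacteria_associated_pool = bact_assoc,
               bacteria_free_pool = bact_free, others_pool = others,
               total_new_N = total,
               host_retained_pct = 100 * host / total,
               fungi_pct = 100 * fungi / total,
               bacteria_associated_pct = 100 * bact_assoc / total,
               bacteria_free_pct = 100 * bact_free / total,
               bacteria_pct = 100 * (bact_assoc + bact_free) / total,
               others_pct = 100 * others / total)
  })
  do.call(rbind, rows)
}

#' Full prevalence scan: retention plus nitrogen fate
#'
#' @inheritParams populationFixation
#' @return data.frame joining [populationFixation()] and [nitrogenFate()]
#'   by \code{P_total}.
#' @export
budgetScan <- function(state, params = budgetParams(),
                       P_scan = seq(0, 11, by = 0.5)) {
  merge(populationFixation(state, params, P_scan),
        nitrogenFate(state, params, P_scan), by = "P_total")
}
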