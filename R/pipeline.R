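#' Quantify a simulated population through the full SIMS pipeline
#'
#' Lays the population's ROIs out over as many simulated rasters as needed,
#' draws ion-count stacks, extracts ROI counts, computes QC'd isotope
#' ratios, estimates the instrument mass-fractionation correction from the
#' non-enriched control ROIs (against the natural-abundance reference), and
#' assembles calibrated per-cell measurements.
#'
#' @param pop Output of [simulatePopulation()].
#' @param scfg A [simsConfig()].
#' @param batch_size ROIs per simulated raster.
#' @param max_se_factor,max_rsd_pct QC thresholds, see [qcEvaluate()].
#' @return List with \code{ratios} (calibrated, QC-evaluated ratio table),
#'   \code{cells} ([cellMeasurements()] table), \code{calibration}, and
#'   \code{qc_report} (rejection counts by reason).
#' @export
quantifyPopulation <- function(pop, scfg = simsConfig(), batch_size = 100,
                               max_se_factor = 2, max_rsd_pct = 25,
                               combine = "both") {
  info <- roiInfo(pop$rois)
  ids <- info$roi_id
  batches <- split(ids, ceiling(seq_along(ids) / batch_size))
  ratio_list <- vector("list", length(batches))
  for (b in seq_along(batches)) {
    r <- rasterizeRois(pop$rois, batches[[b]], scfg)
    stack <- simulateIonStack(r, pop$truth, scfg,
                              seed = deriveSeed(scfg$seed, paste0("batch", b)))
    ratio_list[[b]] <- quantifyStack(stack, r, max_se_factor, max_rsd_pct,
                                     combine)
  }
  ratios <- do.call(rbind, ratio_list)
  ctrl_ids <- info$roi_id[info$category == "control"]
  nat <- naturalRatios()
  calib <- calibrate(
    ratios[ratios$roi_id %in% ctrl_ids, ],
    c("13C" = nat[["r13C"]] / (1 + nat[["r13C"]]),
      "15N" = nat[["r15N"]] / (1 + nat[["r15N"]])))
  ratios <- applyCalibration(ratios, calib)
  cells <- cellMeasurements(ratios, ctrl_ids)
  qc_report <- list(
    n_roi_isotope = nrow(ratios),
    n_fail_poisson = sum(!ratios$qc_pass_poisson),
    n_fail_rsd = sum(!ratios$qc_pass_rsd),
    n_zero_denominator = sum(ratios$rejected_zero_den),
    n_pass = sum(ratios$qc_pass))
  list(ratios = ratios, cells = cells, calibration = calib,
       qc_report = qc_report)
}

# measured sporangium/bacteria group means used for fold contrasts
.transfer_group_means <- function(rois, cells, truth) {
  info <- roiInfo(rois)
  grp <- truth$group[match(cells$roi_id, truth$roi_id)]
  agg <- function(g) {
    sel <- cells$qc_pass & grp %in% g
    data.frame(ape_13C = mean(cells$ape_13C[sel]),
               ape_15N = mean(cells$ape_15N[sel]), n = sum(sel))
  }
  rbind(
    cbind(group = "sporangium_akihet", agg("sporangium_akihet")),
    cbind(group = "bacteria_associated", agg("bacterium_associated")),
    cbind(group = "sporangium_veg", agg("sporangium_veg")))
}

#' Run the full desk-scale analysis pipeline
#'
#' simulate -> quantify -> rates -> transfer -> prevalence -> budget, with
#' a machine-readable summary. All randomness derives from the master seed
#' carried by the configurations.
#'
#' @param cfg A [populationConfig()].
#' @param scfg A [simsConfig()].
#' @param state A [populationState()]; composition and prevalence default
#'   to the configured population.
#' @param params A [budgetParams()].
#' @param out_dir Optional directory; when given, the summary is written to
#'   \code{summary.json} and the main tables to CSV.
#' @param batch_size ROIs per simulated raster.
#' @return List with all stage outputs plus \code{summary}.
#' @export
runPipeline <- function(cfg = populationConfig(), scfg = simsConfig(),
                        state = NULL, params = budgetParams(),
                        out_dir = NULL, batch_size = 100) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  pop <- stage("simulate", simulatePopulation(cfg))
  q <- stage("quantify", quantifyPopulation(pop, scfg, batch_size))
  rates <- stage("rates", cellRates(q$cells, pop$rois, cfg$cell_contents,
                                    cfg$labeling, cfg$dt_days))
  sum_C <- summarizeGroups(rates, "r_C")
  sum_N <- summarizeGroups(rates, "r_N")
  pairs <- stage("transfer", pairHostSporangium(pop$rois, q$cells))
  slopes <- if (nrow(pairs)) originSlope(pairs) else NULL
  gm <- .transfer_group_means(pop$rois, q$cells, pop$truth)
  folds <- groupFoldChanges(gm)
  prev <- stage("prevalence",
                computePrevalence(pop$rois, cfg$cell_length_um))
  if (is.null(state))
    state <- populationState(
      composition = cfg$composition,
      prevalence = cfg$prevalence_by_type,
      cells_per_ml = cfg$cells_per_ml)
  scan <- stage("budget", budgetScan(state, params))

  # bacterial colonization contrast from the simulated ROIs
  info <- roiInfo(pop$rois)
  hosts <- info[info$category %in% .HOST_CATEGORIES, ]
  bact <- info[info$category == "bacterium" & !is.na(info$host_link), ]
  n_bact <- table(factor(bact$host_link, levels = hosts$roi_id))
  zfit <- stage("colonization",
                zinbFit(as.integer(n_bact),
                        group = hosts$infection_status))

  summary <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("parasip")),
    n_rois = nrow(info),
    qc = q$qc_report,
    prevalence = prev[c("filament_prevalence_pct", "cell_prevalence_pct",
                        "total_cell_prevalence_pct", "n_filaments")],
    rate_contrasts_C = sum_C$contrasts,
    rate_contrasts_N = sum_N$contrasts,
    fold_changes = folds,
    colonization = list(model = zfit$model, pi = zfit$pi,
                        rate_ratio = zfit$rate_ratio,
                        rate_ratio_ci = zfit$rate_ratio_ci),
    budget = scan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    utils::write.csv(rates, file.path(out_dir, "cell_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(scan, file.path(out_dir, "budget_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(pairs, file.path(out_dir, "host_parasite_pairs.csv"),
                     row.names = FALSE)
  }
  list(population = pop, quantification = q, rates = rates,
       summaries = list(C = sum_C, N = sum_N), pairs = pairs,
       slopes = slopes, fold_changes = folds, prevalence = prev,
       budget = scan, colonization = zfit, summary = summary)
}

#' Validate tabular pipeline inputs
#'
#' Schema checks for the CSV inputs of the pipeline; returns an empty
#' data.frame when everything is well-formed, otherwise one row per
#' violation naming the file, row and field.
#'
#' @param roi_csv,cells_csv,bulk_csv Optional file paths.
#' @param mask_tif,stack_yaml Optional mask TIFF and stack sidecar to check
#'   for shape agreement.
#' @return data.frame with columns \code{file}, \code{row}, \code{field},
#'   \code{problem}.
#' @export
validateInputs <- function(roi_csv = NULL, cells_csv = NULL,
                           bulk_csv = NULL, mask_tif = NULL,
                           stack_yaml = NULL) {
  v <- data.frame(file = character(), row = integer(), field = character(),
                  problem = character())
  bad <- function(file, row, field, problem)
    rbind(v, data.frame(file = file, row = row, field = field,
                        problem = problem))
  if (!is.null(roi_csv)) {
    x <- utils::read.csv(roi_csv, stringsAsFactors = FALSE)
    for (col in .roi_info_cols)
      if (!col %in% names(x))
        v <- bad(roi_csv, NA, col, "missing column")
    if ("category" %in% names(x)) {
      bad_rows <- which(!x$category %in% roiCategories())
      for (r in bad_rows)
        v <- bad(roi_csv, r, "category",
                 paste0("unknown category '", x$category[r], "'"))
    }
    if ("roi_id" %in% names(x) && anyDuplicated(x$roi_id))
      v <- bad(roi_csv, anyDuplicated(x$roi_id), "roi_id", "duplicate id")
  }
  if (!is.null(cells_csv)) {
    x <- utils::read.csv(cells_csv, stringsAsFactors = FALSE)
    for (col in c("roi_id", "ape_13C", "ape_15N", "qc_pass"))
      if (!col %in% names(x))
        v <- bad(cells_csv, NA, col, "missing column")
  }
  if (!is.null(bulk_csv)) {
    x <- utils::read.csv(bulk_csv, stringsAsFactors = FALSE)
    for (col in c("a_pn", "a_pn0", "a_n", "pn_umol_l", "dt_days"))
      if (!col %in% names(x))
        v <- bad(bulk_csv, NA, col, "missing column")
    if (all(c("a_n", "a_pn0", "labeled") %in% names(x))) {
      bad_rows <- which(x$labeled & x$a_n <= x$a_pn0)
      for (r in bad_rows)
        v <- bad(bulk_csv, r, "a_n", "source pool not enriched (A_N <= A_PN0)")
    }
  }
  if (!is.null(mask_tif) && !is.null(stack_yaml)) {
    stack <- readIonStack(stack_yaml)
    m <- tiff::readTIFF(mask_tif)
    d <- dim(ionCounts(stack, ionSpecies(stack)[1]))[2:3]
    if (!identical(dim(m), d))
      v <- bad(mask_tif, NA, "shape",
               paste0("mask ", paste(dim(m), collapse = "x"),
                      " vs stack planes ", paste(d, collapse = "x")))
  }
  v
}
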