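test_that("weighted prevalence is the composition-weighted mean", {
  # uniform prevalence collapses to that prevalence
  expect_equal(weightedPrevalence(c(v = 0.5, h = 0.3, a = 0.2),
                                  c(0.2, 0.2, 0.2)), 20)
  expect_equal(weightedPrevalence(c(0.91, 0.07, 0.02),
                                  c(0.05, 0.44, 0.82)),
               100 * (0.91 * 0.05 + 0.07 * 0.44 + 0.02 * 0.82),
               tolerance = 1e-12)
  expect_error(weightedPrevalence(c(0.5, 0.4), c(0.1, 0.1)), "sum to 1")
  expect_error(weightedPrevalence(c(0.5, 0.5), c(0.1, 1.1)), "\\[0, 1\\]")
})

test_that("prevalence scenarios scale linearly from the anchor", {
  params <- budgetParams()
  comp <- populationState()$composition
  expect_equal(unname(prevalenceScenario(0, params, comp)),
               c(0, 0, 0))
  P_max <- weightedPrevalence(comp, params$scenario_anchor)
  expect_equal(prevalenceScenario(P_max, params, comp),
               params$scenario_anchor)
  half <- prevalenceScenario(P_max / 2, params, comp)
  expect_equal(half, params$scenario_anchor / 2)
  # scenario consistency across the scan
  for (P in seq(0, P_max, length.out = 23)) {
    p <- prevalenceScenario(P, params, comp)
    expect_equal(weightedPrevalence(comp, p), P, tolerance = 1e-9)
  }
  expect_error(prevalenceScenario(P_max + 1, params, comp), "P_total")
})

test_that("population fixation retention matches the spreadsheet oracle", {
  st <- populationState(); bp <- budgetParams()
  fx <- populationFixation(st, bp, c(0, 11.24))
  expect_equal(fx$retained_C_pct[1], 100)
  expect_equal(fx$retained_N_pct[1], 100)
  # independent spreadsheet-style arithmetic at the anchor scenario
  f <- c(0.91, 0.07, 0.02); p <- c(0.06, 0.54, 1.00) * 11.24 /
    weightedPrevalence(st$composition, bp$scenario_anchor)
  rC_non <- c(0.39, 0.10, 4.5); rC_inf <- c(0.38, 0.08, 3.2)
  rN_non <- c(0.04, 0.018, 0.71); rN_inf <- c(0.04, 0.013, 0.31)
  oracle_C <- sum(f * ((1 - p) * rC_non + p * rC_inf)) / sum(f * rC_non)
  oracle_N <- sum(f * ((1 - p) * rN_non + p * rN_inf)) / sum(f * rN_non)
  expect_equal(fx$retained_C_pct[2], 100 * oracle_C, tolerance = 1e-9)
  expect_equal(fx$retained_N_pct[2], 100 * oracle_N, tolerance = 1e-9)
  # null effect: infected rates equal to non-infected keep 100% at all P
  rt <- budgetRateTable()
  rt$r_C[rt$status == "infected"] <- rt$r_C[rt$status == "non_infected"]
  rt$r_N[rt$status == "infected"] <- rt$r_N[rt$status == "non_infected"]
  bp_null <- budgetParams(rate_table = rt)
  fx_null <- populationFixation(st, bp_null, seq(0, 11, by = 1))
  expect_true(all(abs(fx_null$retained_C_pct - 100) < 1e-9))
  expect_true(all(abs(fx_null$retained_N_pct - 100) < 1e-9))
  expect_true(all(abs(fx_null$cn_retained - fx_null$cn_retained[1]) < 1e-9))
})

test_that("nitrogen fate conserves mass and orders pools correctly", {
  st <- populationState(); bp <- budgetParams()
  scan <- nitrogenFate(st, bp, seq(0, 11, by = 0.5))
  sums <- scan$host_retained_pct + scan$fungi_pct +
    scan$bacteria_associated_pct + scan$bacteria_free_pct + scan$others_pct
  expect_true(all(abs(sums - 100) <= 0.01))
  # fungal share strictly increasing with prevalence
  expect_true(all(diff(scan$fungi_pct) > 0))
  # associated bacteria are a negligible share of the bacterial pool
  expect_lt(max(scan$bacteria_associated_pct / scan$bacteria_pct), 0.01)
  # zero sporangium uptake removes the fungal pool
  bp0 <- budgetParams(sporangium_N_uptake = 0)
  expect_equal(nitrogenFate(st, bp0, 9)$fungi_pct, 0)
  # named pools exceeding the total is a configuration error
  bp_bad <- budgetParams(total_new_N = 50)
  expect_error(nitrogenFate(st, bp_bad, 11), "configuration error")
})

test_that("retention declines and the retained C:N ratio rises with prevalence", {
  st <- populationState(); bp <- budgetParams()
  fx <- populationFixation(st, bp, seq(0, 11, by = 0.25))
  expect_true(all(diff(fx$retained_N_pct) <= 1e-12))
  expect_true(all(diff(fx$retained_C_pct) <= 1e-12))
  expect_true(all(diff(fx$cn_retained) > 0))
  expect_equal(cnRetainedRatio(st, bp, 0), fx$cn_retained[1])
})

test_that("observed prevalence respects the four-cell filament definition", {
  # a 3-cell chain carrying a sporangium is not a filament at all
  short_info <- data.frame(
    roi_id = 1:8,
    category = c(rep("vegetative", 3), rep("vegetative", 4), "sporangium"),
    sporangial_stage = c(rep("none", 7), "mature"),
    host_link = c(rep(NA_character_, 7), "1"),
    filament_id = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 1L),
    centroid_x_um = 1:8, centroid_y_um = 0,
    min_distance_to_host_cell_um = 0,
    infection_status = c("infected", rep("non_infected", 6), NA))
  rois <- ROISet(mask = matrix(0L, 1, 1), info = short_info)
  prev <- computePrevalence(rois)
  expect_equal(prev$n_filaments, 1L)
  expect_equal(prev$filament_prevalence_pct, 0)
  expect_equal(unname(prev$cell_prevalence_pct["vegetative"]), 0)

  # no sporangia anywhere -> zero prevalence at all levels
  cfg0 <- populationConfig(n_cells = 300,
                           prevalence_by_type = c(vegetative = 0,
                                                  heterocyte = 0,
                                                  akinete = 0), seed = 2)
  prev0 <- computePrevalence(simulatePopulation(cfg0)$rois)
  expect_equal(prev0$filament_prevalence_pct, 0)
  expect_equal(prev0$total_cell_prevalence_pct, 0)

  # simulated population recovers configured prevalences within 95% CIs
  cfg <- populationConfig(n_cells = 4000, seed = 55)
  pop <- simulatePopulation(cfg)
  prev <- computePrevalence(pop$rois)
  info <- roiInfo(pop$rois)
  cells <- info[info$category %in% c("vegetative", "heterocyte_I",
                                     "heterocyte_II", "akinete_I",
                                     "akinete_II"), ]
  type <- ifelse(grepl("^het", cells$category), "heterocyte",
                 ifelse(grepl("^aki", cells$category), "akinete",
                        "vegetative"))
  for (t in c("vegetative", "heterocyte", "akinete")) {
    n_t <- sum(type == t)
    k <- round(prev$cell_prevalence_pct[[t]] / 100 * n_t)
    ci <- binom.test(k, n_t)$conf.int
    expect_true(cfg$prevalence_by_type[[t]] >= ci[1] - 0.02 &&
                  cfg$prevalence_by_type[[t]] <= ci[2] + 0.02)
  }
})
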