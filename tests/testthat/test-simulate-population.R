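test_that("degenerate prevalence and determinism behave as specified", {
  cfg <- populationConfig(n_cells = 400,
                          prevalence_by_type = c(vegetative = 0,
                                                 heterocyte = 0,
                                                 akinete = 0),
                          seed = 3)
  pop <- simulatePopulation(cfg)
  expect_equal(sum(roiInfo(pop$rois)$category == "sporangium"), 0L)

  cfg2 <- populationConfig(n_cells = 400, seed = 5)
  a <- simulatePopulation(cfg2)
  b <- simulatePopulation(cfg2)
  expect_identical(roiInfo(a$rois), roiInfo(b$rois))
  expect_identical(a$truth, b$truth)

  expect_error(populationConfig(composition = c(vegetative = 0.9,
                                                heterocyte = 0.2,
                                                akinete = 0.02)),
               "sum to 1")
})

test_that("realized composition and prevalence sit in exact binomial 99% CIs", {
  cfg <- populationConfig(n_cells = 10000, seed = 101)
  pop <- simulatePopulation(cfg)
  info <- roiInfo(pop$rois)
  cells <- info[info$category %in% c("vegetative", "heterocyte_I",
                                     "heterocyte_II", "akinete_I",
                                     "akinete_II"), ]
  type <- ifelse(grepl("^het", cells$category), "heterocyte",
                 ifelse(grepl("^aki", cells$category), "akinete",
                        "vegetative"))
  n <- nrow(cells)
  for (t in names(cfg$composition)) {
    k <- sum(type == t)
    p <- cfg$composition[[t]]
    expect_gte(k, qbinom(0.005, n, p))
    expect_lte(k, qbinom(0.995, n, p))
  }
  for (t in names(cfg$prevalence_by_type)) {
    sel <- type == t
    k <- sum(cells$infection_status[sel] == "infected")
    p <- cfg$prevalence_by_type[[t]]
    expect_gte(k, qbinom(0.005, sum(sel), p))
    expect_lte(k, qbinom(0.995, sum(sel), p))
  }
})

test_that("infected and non-infected filament lengths match their targets", {
  cfg <- populationConfig(n_cells = 22000, seed = 202)
  pop <- simulatePopulation(cfg)
  prev <- computePrevalence(pop$rois, cfg$cell_length_um)
  fl <- prev$filament_lengths
  for (grp in c(TRUE, FALSE)) {
    x <- fl$length_um[fl$infected == grp]
    target <- if (grp) 272 else 99
    expect_gte(length(x), 250)
    sem <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - target), 2 * sem + cfg$cell_length_um / 2)
  }
  # infected filaments are substantially longer
  expect_gt(mean(fl$length_um[fl$infected]),
            2 * mean(fl$length_um[!fl$infected]))
})

test_that("sporangium bookkeeping conserves hosts and infections", {
  cfg <- populationConfig(n_cells = 2000, seed = 77)
  pop <- simulatePopulation(cfg)
  info <- roiInfo(pop$rois)
  spor <- info[info$category == "sporangium", ]
  hosts_linked <- lapply(spor$host_link, parasip:::.parse_host_link)
  # every sporangium resolves to at least one existing host cell
  expect_true(all(vapply(hosts_linked, length, 1L) >= 1L))
  expect_true(all(unlist(hosts_linked) %in% info$roi_id))
  host_cat <- info$category[match(unlist(hosts_linked), info$roi_id)]
  expect_true(all(host_cat %in% c("vegetative", "heterocyte_I",
                                  "heterocyte_II", "akinete_I",
                                  "akinete_II")))
  # every infected cell is claimed by at least one sporangium
  infected_ids <- info$roi_id[info$infection_status %in% "infected"]
  expect_setequal(intersect(infected_ids, unlist(hosts_linked)),
                  infected_ids)
  # junction sporangia link an akinete with a heterocyte
  two_hosts <- hosts_linked[vapply(hosts_linked, length, 1L) == 2L]
  for (h in two_hosts) {
    cats <- sort(info$category[match(h, info$roi_id)])
    expect_identical(cats, c("akinete_I", "heterocyte_I"))
  }
})

test_that("zero-inflated colonization counts have the configured structure", {
  expect_identical(simulateBacteriaCounts(50, pi = 1, mu = 2, k = 1,
                                          seed = 1),
                   rep(0L, 50))
  # Poisson limit: large k, no inflation
  y <- simulateBacteriaCounts(5000, pi = 0, mu = 3, k = 1e6, seed = 2)
  expect_lt(abs(mean(y) - 3), 3 * sd(y) / sqrt(length(y)))
  # the two colonization groups reproduce 0.2 and 1.7 bacteria per cell;
  # the SEM comes from the parametric ZINB variance
  # (1-pi) mu (1 + mu/k) + pi (1-pi) mu^2
  zinb_sd <- function(pi, mu, k)
    sqrt((1 - pi) * mu * (1 + mu / k) + pi * (1 - pi) * mu^2)
  g_non <- simulateBacteriaCounts(100, 0.6, 0.5, 1.0, seed = 31)
  g_inf <- simulateBacteriaCounts(100, 0.6, 4.25, 1.31, seed = 32)
  expect_lt(abs(mean(g_non) - 0.2), 2 * zinb_sd(0.6, 0.5, 1.0) / 10)
  expect_lt(abs(mean(g_inf) - 1.7), 2 * zinb_sd(0.6, 4.25, 1.31) / 10)
  expect_error(simulateBacteriaCounts(10, -0.1, 1, 1), "pi")
  expect_error(simulateBacteriaCounts(10, 0.5, -1, 1), "mu")
})

test_that("bulk bottle simulation inverts exactly and stores the amendment", {
  s <- simulateBulkSamples(n_labeled = 9, n_control = 3, true_rate = 0.21,
                           noise_sd = 0, seed = 9)
  expect_equal(nrow(s), 12L)
  expect_equal(sum(!s$labeled), 3L)
  # controls carry no amendment
  expect_equal(s$a_n[!s$labeled], s$a_pn0[!s$labeled])
  # forward/inverse identity at zero noise
  lab <- s[s$labeled, ]
  expect_equal(bulkFixationRate(lab), rep(0.21, 9), tolerance = 1e-12)
  # source-pool enrichment matches the configured 0.67 at% excess
  expect_equal(lab$a_n - lab$a_pn0, rep(0.0067, 9), tolerance = 1e-12)
})
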