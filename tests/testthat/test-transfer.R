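make_pair_fixture <- function() {
  # filament: veg - het_I - aki_I - veg; sporangium 5 on the junction,
  # sporangium 6 on the first vegetative cell
  extra <- data.frame(
    roi_id = 5:6, category = "sporangium",
    sporangial_stage = "mature",
    host_link = c("2;3", "1"), filament_id = 1L,
    centroid_x_um = c(12, 5), centroid_y_um = 12,
    min_distance_to_host_cell_um = 0, infection_status = NA_character_)
  rois <- make_roiset(c("vegetative", "heterocyte_I", "akinete_I",
                        "vegetative"),
                      infected = c(TRUE, TRUE, TRUE, FALSE),
                      extra = extra)
  cells <- data.frame(
    roi_id = 1:6,
    at_pct_13C = 0, at_pct_15N = 0,
    ape_13C = c(1.5, 0.25, 1.0, 0.30, 1.0, 0.32),
    ape_15N = c(0.33, 0.07, 0.11, 0.03, 0.25, 0.046),
    qc_pass = TRUE)
  list(rois = rois, cells = cells)
}

test_that("sporangium-host pairing expands junctions and honors QC", {
  fx <- make_pair_fixture()
  pairs <- pairHostSporangium(fx$rois, fx$cells)
  # one junction sporangium (2 rows) + one vegetative sporangium (1 row)
  expect_equal(nrow(pairs), 3L)
  expect_equal(sum(pairs$sporangium_roi == 5), 2L)
  expect_setequal(pairs$host_category[pairs$sporangium_roi == 5],
                  c("heterocyte_I", "akinete_I"))
  # pairing conservation: n(pairs) = singles + 2 * junctions - dropped
  expect_equal(nrow(pairs), 1L + 2L * 1L - attr(pairs, "n_dropped"))

  # QC-failed host drops its pair and is counted
  cells2 <- fx$cells; cells2$qc_pass[1] <- FALSE
  pairs2 <- pairHostSporangium(fx$rois, cells2)
  expect_equal(nrow(pairs2), 2L)
  expect_equal(attr(pairs2, "n_dropped"), 1L)
})

test_that("pairwise APE ratios match hand arithmetic and guard the zero host", {
  p <- data.frame(ape_13C_sporangium = c(1.0, 1.0, 0.07, 0.5),
                  ape_13C_host = c(1.0, 0.25, 0.33, 0),
                  ape_15N_sporangium = 0.2, ape_15N_host = 0.1)
  out <- apeRatio(p)
  expect_equal(out$ratio_13C[1], 1)
  expect_equal(out$ratio_13C[2], 4.0)
  expect_equal(out$ratio_13C[3], 0.07 / 0.33, tolerance = 1e-12)
  expect_true(is.na(out$ratio_13C[4]))
  expect_equal(out$ratio_15N, rep(2, 4))
})

test_that("fold contrasts use ratios of group means with cross-isotope minima", {
  gm <- data.frame(group = c("sporangia_akihet", "bacteria", "sporangia_veg"),
                   ape_13C = c(1.42, 0.59, 0.32),
                   ape_15N = c(0.25, 0.08, 0.02))
  f <- groupFoldChanges(gm)
  sb <- f[f$numerator == "sporangia_akihet" & f$denominator == "bacteria", ]
  expect_equal(sb$fold_13C, 1.42 / 0.59, tolerance = 1e-12)
  expect_equal(sb$fold_15N, 0.25 / 0.08, tolerance = 1e-12)
  expect_equal(sb$fold_min, 1.42 / 0.59, tolerance = 1e-12)
  bv <- f[f$numerator == "bacteria" & f$denominator == "sporangia_veg", ]
  expect_equal(bv$fold_min, 0.59 / 0.32, tolerance = 1e-12)
  # identical groups give fold 1
  same <- groupFoldChanges(data.frame(group = c("a", "b"), ape_13C = 1,
                                      ape_15N = 1))
  expect_true(all(same$fold_min == 1))
})

test_that("origin slopes equal the mean of per-pair ratios", {
  p <- data.frame(host_category = "vegetative",
                  ape_13C_sporangium = c(2, 4) * 0.3,
                  ape_13C_host = 0.3,
                  ape_15N_sporangium = c(0.21, 0.21) * 0.1,
                  ape_15N_host = 0.1)
  p <- apeRatio(p)
  s <- originSlope(p)
  expect_equal(s$slope[s$isotope == "13C"], 3)       # mean of {2, 4}
  expect_equal(s$slope[s$isotope == "15N"], 0.21, tolerance = 1e-12)
  expect_equal(s$n_pairs, c(2L, 2L))
})

test_that("zero-inflated fits recover parameters and beat the grid oracle", {
  y <- simulateBacteriaCounts(800, pi = 0.55, mu = 2.0, k = 0.7, seed = 61)
  f <- zinbFit(y)
  expect_true(f$converged)
  expect_identical(f$model, "zinb")
  expect_equal(f$aic, 2 * length(f$coef) - 2 * f$loglik, tolerance = 1e-9)
  # fitted optimum dominates a dense grid of the independent log-likelihood
  grid <- expand.grid(pi = seq(0.35, 0.75, by = 0.02),
                      mu = seq(1.2, 3.0, by = 0.05),
                      k = seq(0.3, 1.4, by = 0.05))
  best <- max(vapply(seq_len(nrow(grid)), function(i)
    oracle_zi_loglik(y, grid$pi[i], grid$mu[i], grid$k[i]), numeric(1)))
  expect_gte(f$loglik, best - 1e-6)

  # degenerate all-zero input hits the boundary with a finite loglik
  f0 <- zinbFit(rep(0L, 40))
  expect_equal(f0$pi, 1)
  expect_true(is.finite(f0$loglik))
  expect_true(f0$converged)
  expect_error(zinbFit(c(-1L, 2L)), "non-negative")
})

test_that("the ZINB fit agrees with an independent mixed-model implementation", {
  y <- simulateBacteriaCounts(1500, pi = 0.5, mu = 2.2, k = 0.9, seed = 88)
  f <- zinbFit(y)
  g <- glmmTMB::glmmTMB(y ~ 1, ziformula = ~1, family = glmmTMB::nbinom2,
                        data = data.frame(y = y))
  expect_equal(f$loglik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
  expect_equal(f$pi, stats::plogis(glmmTMB::fixef(g)$zi[[1]]),
               tolerance = 1e-3)
  expect_equal(f$mu, exp(glmmTMB::fixef(g)$cond[[1]]), tolerance = 1e-3)
  expect_equal(f$k, glmmTMB::sigma(g), tolerance = 1e-2)
})

test_that("rate-ratio intervals cover the true contrast in most replicates", {
  # colonization contrast with true count-component rate ratio 0.11
  n_rep <- 200
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    inf <- simulateBacteriaCounts(100, 0.6, 4.25, 1.31, seed = 1000 + i)
    non <- simulateBacteriaCounts(100, 0.6, 4.25 * 0.11, 1.31,
                                  seed = 5000 + i)
    f <- zinbFit(c(inf, non), rep(c("infected", "non_infected"), each = 100))
    ci <- f$rate_ratio_ci
    covered[i] <- !anyNA(ci) && ci[1] <= 0.11 && 0.11 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
})
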