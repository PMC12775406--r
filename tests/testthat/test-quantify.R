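test_that("ratio arithmetic and Poisson error follow the counting formulas", {
  # nano mode carries the x0.5 factor of the C2- denominator
  np <- 5
  tab <- rbind(
    data.frame(roi_id = 1L, species = "12C13C", plane = 1:np,
               counts = c(20L, 20L, 20L, 20L, 20L)),
    data.frame(roi_id = 1L, species = "12C12C", plane = 1:np,
               counts = rep(2000L, np)),
    data.frame(roi_id = 1L, species = "15N12C", plane = 1:np,
               counts = rep(100L, np)),
    data.frame(roi_id = 1L, species = "14N12C", plane = 1:np,
               counts = rep(10000L, np)))
  r <- computeRatio(tab, "nano")
  expect_equal(r$R[r$isotope == "13C"], 0.0050)
  # sigma = R * sqrt(1/N_num + 1/N_den) on the quoted 500/50000 example
  r15 <- r[r$isotope == "15N", ]
  expect_equal(r15$R, 0.01)
  expect_equal(r15$sigma_poisson, 0.01 * sqrt(1 / 500 + 1 / 50000),
               tolerance = 1e-12)

  # zero numerator: R = 0 retained, sigma uses the one-count floor
  tab0 <- rbind(
    data.frame(roi_id = 1L, species = "13C14N", plane = 1:np, counts = 0L),
    data.frame(roi_id = 1L, species = "12C14N", plane = 1:np,
               counts = rep(1000L, np)),
    data.frame(roi_id = 1L, species = "12C15N", plane = 1:np, counts = 0L))
  r0 <- computeRatio(tab0, "large_geometry")
  row <- r0[r0$isotope == "13C", ]
  expect_equal(row$R, 0)
  expect_false(row$rejected_zero_den)
  # one-count floor: sigma stays finite and positive at zero counts
  expect_equal(row$sigma_poisson, (1 / 5000) * sqrt(1 + 1 / 5000),
               tolerance = 1e-12)

  # zero denominator: rejected outright
  tabz <- rbind(
    data.frame(roi_id = 1L, species = "13C14N", plane = 1:np, counts = 1L),
    data.frame(roi_id = 1L, species = "12C14N", plane = 1:np, counts = 0L),
    data.frame(roi_id = 1L, species = "12C15N", plane = 1:np, counts = 0L))
  rz <- qcEvaluate(computeRatio(tabz, "large_geometry"))
  expect_true(all(rz$rejected_zero_den))
  expect_false(any(rz$qc_pass))

  # missing species is an input error
  expect_error(computeRatio(tab0[tab0$species != "12C15N", ],
                            "large_geometry"), "input error")
})

test_that("QC thresholds reject on the stated boundaries", {
  base <- data.frame(roi_id = 1:4, isotope = "13C", N_num = 100,
                     N_den = 10000, R = 0.01,
                     sigma_poisson = 1e-3,
                     se_planes = c(2.5e-3, 1.0e-3, 1.0e-3, 2.0e-3),
                     rsd_planes = c(10, 26, 10, 25),
                     n_planes_used = 50L, n_planes_dropped = 0L,
                     rejected_zero_den = FALSE,
                     qc_pass_poisson = NA, qc_pass_rsd = NA, qc_pass = NA)
  q <- qcEvaluate(base, max_se_factor = 2, max_rsd_pct = 25,
                  combine = "either")
  # se = 2.5 sigma fails the Poisson criterion
  expect_false(q$qc_pass_poisson[1])
  # rsd = 26% fails the RSD criterion
  expect_false(q$qc_pass_rsd[2])
  # boundary values (se = 2 sigma, rsd = 25%) still pass
  expect_true(q$qc_pass_poisson[4])
  expect_true(q$qc_pass_rsd[4])
  # well within both -> pass
  expect_true(q$qc_pass[3])
  # under the either rule a single failure rejects
  expect_false(q$qc_pass[1])
  expect_false(q$qc_pass[2])
  # under the conjunction rule a single failure is tolerated
  q2 <- qcEvaluate(base, combine = "both")
  expect_true(q2$qc_pass[1])
  expect_true(q2$qc_pass[2])
  expect_false(qcEvaluate(transform(base, se_planes = 3e-3,
                                    rsd_planes = 30),
                          combine = "both")$qc_pass[1])
})

test_that("inflating per-plane variance at fixed totals only flips QC to fail", {
  # per-plane series with identical cumulative counts but growing spread
  np <- 10L
  den <- rep(5000L, np)
  spreads <- list(rep(50L, np),
                  rep(c(45L, 55L), np / 2),
                  rep(c(30L, 70L), np / 2),
                  rep(c(10L, 90L), np / 2),
                  rep(c(0L, 100L), np / 2))
  passed <- vapply(spreads, function(num) {
    tab <- rbind(
      data.frame(roi_id = 1L, species = "13C14N", plane = 1:np,
                 counts = num),
      data.frame(roi_id = 1L, species = "12C14N", plane = 1:np,
                 counts = den),
      data.frame(roi_id = 1L, species = "12C15N", plane = 1:np,
                 counts = 18L))
    q <- qcEvaluate(computeRatio(tab, "large_geometry"),
                    combine = "either")
    q$qc_pass[q$isotope == "13C"]
  }, logical(1))
  expect_false(is.unsorted(rev(passed)))   # monotone TRUE ... FALSE
  expect_true(passed[1])
  expect_false(passed[length(passed)])
})

test_that("calibration is exact arithmetic and idempotent on controls", {
  ctrl <- data.frame(roi_id = 1:3, isotope = "13C",
                     N_num = 100, N_den = 10000,
                     R = c(0.0099, 0.0100, 0.0101),
                     sigma_poisson = 1e-4, se_planes = 1e-4,
                     rsd_planes = 5, n_planes_used = 50L,
                     n_planes_dropped = 0L, rejected_zero_den = FALSE,
                     qc_pass_poisson = TRUE, qc_pass_rsd = TRUE,
                     qc_pass = TRUE)
  ref_frac <- 0.0112 / 1.0112    # atom fraction of a 0.0112 ratio
  cal <- calibrate(ctrl, c("13C" = ref_frac))
  expect_equal(cal$alpha, 1.12, tolerance = 1e-12)
  # applied to a sample ratio of 0.0050
  samp <- transform(ctrl[1, ], R = 0.0050)
  expect_equal(applyCalibration(samp, cal)$R, 0.0056, tolerance = 1e-12)
  # R = 0 is preserved under any alpha
  expect_equal(applyCalibration(transform(ctrl[1, ], R = 0), cal)$R, 0)
  # identity when measured equals reference
  cal_id <- calibrate(transform(ctrl, R = 0.0112), c("13C" = ref_frac))
  expect_equal(cal_id$alpha, 1, tolerance = 1e-12)
  # idempotence: corrected mean control ratio maps onto the reference
  corrected <- mean(ctrl$R) * cal$alpha
  expect_equal(toAtomPercent(corrected) / (100 * ref_frac), 1,
               tolerance = 1e-9)
  # no passing controls is a calibration error
  expect_error(calibrate(transform(ctrl, qc_pass = FALSE),
                         c("13C" = ref_frac)), "calibration error")
})

test_that("atom-percent algebra and APE baseline behave as stated", {
  expect_equal(toAtomPercent(0), 0)
  expect_equal(toAtomPercent(1), 50)
  expect_equal(toAtomPercent(0.0112372), 100 * 0.0112372 / 1.0112372,
               tolerance = 1e-12)
  r <- c(0, 0.001, 0.0112372, 0.5, 3)
  expect_equal(ratioFromAtomPercent(toAtomPercent(r)), r, tolerance = 1e-12)
  expect_error(toAtomPercent(-0.1), "input error")
  expect_true(all(diff(toAtomPercent(seq(0, 2, by = 0.01))) > 0))

  expect_equal(computeApe(4.9, 1.1), 3.8)
  expect_equal(computeApe(1.1, 1.1), 0)
  expect_lt(computeApe(1.0, 1.1), 0)   # retained, not clipped
  expect_error(computeApe(1, NA_real_), "control")
})

test_that("bacteria split at the inclusive 10 um free-living boundary", {
  extra <- data.frame(
    roi_id = 11:14, category = "bacterium", sporangial_stage = "none",
    host_link = c("1", "1", NA, NA), filament_id = NA_integer_,
    centroid_x_um = 0, centroid_y_um = 0,
    min_distance_to_host_cell_um = c(5, 12, 10, NA),
    infection_status = NA_character_)
  rois <- make_roiset(c("vegetative", "vegetative"), extra = extra)
  out <- roiInfo(classifyFreeLiving(rois))
  cls <- out$bacterial_class[match(11:14, out$roi_id)]
  expect_identical(cls, c("associated", "free_living", "free_living",
                          "unclassified"))
  expect_true(all(is.na(out$bacterial_class[out$category != "bacterium"])))
})
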