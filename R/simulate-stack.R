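#' Lay population ROIs out on an analysis raster
#'
#' Places the selected ROIs as ellipses on a square label image, one ROI per
#' grid tile. The ellipse geometry is cosmetic: downstream quantification
#' uses mask membership only. Raises a geometry error when the requested
#' ROIs do not fit the raster.
#'
#' @param rois An [ROISet-class] (mask may be empty).
#' @param roi_ids Which ROI ids to place; defaults to all.
#' @param scfg A [simsConfig()] providing raster geometry.
#' @return An [ROISet-class] whose mask holds the placed ROIs and whose
#'   info table is restricted to them (centroids updated to raster
#'   coordinates in um).
#' @export
rasterizeRois <- function(rois, roi_ids = NULL, scfg = simsConfig()) {
  info <- roiInfo(rois)
  if (is.null(roi_ids)) roi_ids <- info$roi_id
  if (!all(roi_ids %in% info$roi_id))
    stop("unknown roi_ids requested")
  info <- info[match(roi_ids, info$roi_id), , drop = FALSE]
  n <- nrow(info)
  px <- scfg$raster_px
  nt <- ceiling(sqrt(n))
  s <- px %/% nt
  if (s < 4L)
    stop("geometry error: ", n, " ROIs do not fit a ", px, "x", px,
         " raster (tile side ", s, " px < 4 px)")
  mask <- matrix(0L, px, px)
  rx <- max(1.4, s * 0.32); ry <- max(1.1, s * 0.26)
  pix_um <- scfg$raster_um / px
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    ti <- (i - 1L) %/% nt; tj <- (i - 1L) %% nt
    c_row <- ti * s + s / 2 + 0.5; c_col <- tj * s + s / 2 + 0.5
    rows <- max(1L, floor(c_row - ry)):min(px, ceiling(c_row + ry))
    cols <- max(1L, floor(c_col - rx)):min(px, ceiling(c_col + rx))
    rr <- outer((rows - c_row)^2 / ry^2, (cols - c_col)^2 / rx^2, "+")
    sel <- which(rr <= 1, arr.ind = TRUE)
    mask[cbind(rows[sel[, 1]], cols[sel[, 2]])] <- info$roi_id[i]
    cx[i] <- c_col * pix_um; cy[i] <- c_row * pix_um
  }
  info$centroid_x_um <- cx
  info$centroid_y_um <- cy
  ROISet(mask = mask, info = info)
}

.stack_species <- function(instrument) {
  if (instrument == "large_geometry") {
    list(species = c("12C14N", "13C14N", "12C15N"),
         den_C = "12C14N", num_C = "13C14N",
         den_N = "12C14N", num_N = "12C15N", c_factor = 1)
  } else {
    list(species = c("12C12C", "12C13C", "14N12C", "15N12C"),
         den_C = "12C12C", num_C = "12C13C",
         den_N = "14N12C", num_N = "15N12C", c_factor = 2)
  }
}

#' Simulate a multi-plane ion-count stack for an ROI mask
#'
#' Per pixel and plane, counts for each recorded ion species are drawn from
#' Poisson distributions whose rates encode each ROI's true isotope ratios
#' (from the truth table, converted from atom-percent excess and multiplied
#' by the instrument mass-fractionation factor) at the configured count
#' depth. Background pixels receive a low flat rate. For the nano
#' instrument, the 12C13C numerator rate carries the factor 2 implied by
#' the two carbon positions of the C2- ion.
#'
#' @param rois An [ROISet-class] with a non-empty mask (see
#'   [rasterizeRois()]).
#' @param truth Ground-truth table from [simulatePopulation()].
#' @param scfg A [simsConfig()].
#' @param seed Seed for the count draws; defaults to \code{scfg$seed}.
#' @return An [IonCountStack-class].
#' @export
simulateIonStack <- function(rois, truth, scfg = simsConfig(),
                             seed = scfg$seed) {
  mask <- roiMask(rois)
  info <- roiInfo(rois)
  ids <- info$roi_id
  if (!all(ids %in% mask))
    stop("geometry error: ROIs outside the raster mask: ",
         paste(setdiff(ids, unique(as.integer(mask))), collapse = ", "))
  ti <- match(ids, truth$roi_id)
  if (anyNA(ti)) stop("truth table lacks rows for some ROIs")

  nat13 <- scfg$natural_ratio_13C; nat15 <- scfg$natural_ratio_15N
  at13 <- 100 * nat13 / (1 + nat13) + truth$true_ape13C[ti]
  at15 <- 100 * nat15 / (1 + nat15) + truth$true_ape15N[ti]
  r13 <- at13 / (100 - at13) * scfg$instrument_alpha
  r15 <- at15 / (100 - at15) * scfg$instrument_alpha

  sp <- .stack_species(scfg$instrument)
  npx <- vapply(ids, function(id) sum(mask == id), 0L)
  if (any(npx == 0L)) stop("geometry error: empty ROI in mask")
  lam_den <- scfg$mean_counts_per_roi / (scfg$n_planes * npx)
  bg <- scfg$background_frac * scfg$mean_counts_per_roi /
    (scfg$n_planes * mean(npx))

  nr <- nrow(mask); nc <- ncol(mask); np <- scfg$n_planes
  roi_index <- match(as.integer(mask), ids)   # NA on background
  rate_img <- function(per_roi_rate) {
    v <- per_roi_rate[roi_index]
    v[is.na(v)] <- bg
    v
  }
  lam <- list()
  lam[[sp$den_C]] <- rate_img(lam_den)
  lam[[sp$num_C]] <- rate_img(lam_den * r13 * sp$c_factor) * 1
  if (sp$den_N != sp$den_C) lam[[sp$den_N]] <- rate_img(lam_den)
  lam[[sp$num_N]] <- rate_img(lam_den * r15)
  # numerator background tracks natural abundance
  lam[[sp$num_C]][is.na(roi_index)] <- bg * nat13 * sp$c_factor
  lam[[sp$num_N]][is.na(roi_index)] <- bg * nat15

  counts <- withSeed(deriveSeed(seed, "stack"), {
    out <- list()
    for (s in sp$species) {
      out[[s]] <- array(
        stats::rpois(np * nr * nc, rep(lam[[s]], each = np)),
        dim = c(np, nr, nc))
    }
    out
  })
  IonCountStack(counts = counts, pixelSizeUm = scfg$raster_um / nr,
                instrument = scfg$instrument)
}

#' Simulate bulk incubation-bottle samples
#'
#' Builds a set of bottles (labeled plus non-amended controls) with the
#' symbols of the bulk tracer model: particulate-pool atom fraction before
#' (\code{a_pn0}) and after (\code{a_pn}) incubation, source-pool atom
#' fraction (\code{a_n}), particulate pool size and incubation duration.
#' \code{a_pn} is computed forward from a chosen true fixation rate plus
#' measurement noise, so that inverting with [bulkFixationRate()] recovers
#' the true rate when the noise is zero.
#'
#' @param n_labeled,n_control Numbers of amended and control bottles.
#' @param labeling_ape Source-pool enrichment in atom percent excess
#'   (default 0.67, the 15N2 amendment).
#' @param a_pn0 Initial particulate atom fraction (defaults to natural 15N
#'   abundance).
#' @param pn_umol_l Particulate pool concentration (umol L-1).
#' @param true_rate True fixation rate (umol L-1 d-1).
#' @param dt_days Incubation duration (d).
#' @param noise_sd Gaussian measurement noise on \code{a_pn} (atom
#'   fraction).
#' @param seed RNG seed.
#' @return data.frame with one row per bottle.
#' @export
simulateBulkSamples <- function(n_labeled = 9, n_control = 3,
                                labeling_ape = 0.67,
                                a_pn0 = naturalRatios()[["r15N"]] /
                                  (1 + naturalRatios()[["r15N"]]),
                                pn_umol_l = 1.0, true_rate = 0.1,
                                dt_days = 0.875, noise_sd = 0,
                                seed = 1L) {
  if (labeling_ape <= 0) stop("labeling level must be > 0")
  if (pn_umol_l <= 0 || dt_days <= 0) stop("pn and dt must be > 0")
  withSeed(deriveSeed(seed, "bulk"), {
    n <- n_labeled + n_control
    labeled <- rep(c(TRUE, FALSE), c(n_labeled, n_control))
    a_n <- ifelse(labeled, a_pn0 + labeling_ape / 100, a_pn0)
    a_pn <- a_pn0 +
      ifelse(labeled, true_rate * dt_days / pn_umol_l * (a_n - a_pn0), 0) +
      stats::rnorm(n, 0, noise_sd)
    data.frame(bottle_id = seq_len(n), labeled = labeled,
               a_pn = a_pn, a_pn0 = a_pn0, a_n = a_n,
               pn_umol_l = pn_umol_l, dt_days = dt_days,
               true_rate = ifelse(labeled, true_rate, 0))
  })
}
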