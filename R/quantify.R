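#' Extract per-ROI, per-plane ion counts
#'
#' Sums ion counts over the mask pixels of every ROI, separately per plane
#' and ion species. Counts are exact integer sums; annotated ROIs with zero
#' mask pixels are flagged in the \code{"empty_rois"} attribute and omitted
#' from the table.
#'
#' @param stack An [IonCountStack-class].
#' @param rois An [ROISet-class] whose mask matches the stack's plane shape.
#' @return Long data.frame with columns \code{roi_id}, \code{species},
#'   \code{plane}, \code{counts}; attribute \code{empty_rois} lists ids of
#'   empty ROIs.
#' @export
extractRoiCounts <- function(stack, rois) {
  mask <- roiMask(rois)
  d <- dim(ionCounts(stack, ionSpecies(stack)[1]))
  if (!identical(dim(mask), d[2:3]))
    stop("geometry error: mask shape ", paste(dim(mask), collapse = "x"),
         " does not match stack plane shape ", paste(d[2:3], collapse = "x"))
  ids <- roiInfo(rois)$roi_id
  maskvec <- as.integer(mask)
  sel <- which(maskvec > 0L & maskvec %in% ids)
  empty <- setdiff(ids, unique(maskvec[sel]))
  np <- d[1]
  out <- vector("list", length(ionSpecies(stack)))
  for (i in seq_along(ionSpecies(stack))) {
    sp <- ionSpecies(stack)[i]
    m <- matrix(ionCounts(stack, sp), nrow = np)   # planes x pixels
    agg <- rowsum(t(m[, sel, drop = FALSE]), group = maskvec[sel])  # roi x plane
    out[[i]] <- data.frame(
      roi_id = rep(as.integer(rownames(agg)), np),
      species = sp,
      plane = rep(seq_len(np), each = nrow(agg)),
      counts = as.vector(agg))
  }
  res <- do.call(rbind, out)
  attr(res, "empty_rois") <- empty
  res
}

#' Compute QC-ready isotope ratios from cumulative ion counts
#'
#' For every ROI and isotope, the ratio is computed from the cumulative
#' counts over all accepted planes: 13C/12C = 13C14N / 12C14N (large
#' geometry) or 12C13C / 12C2 x 0.5 (nano), and 15N/14N = 15N12C / 14N12C.
#' The Poisson counting-statistics error is
#' \code{sigma = R * sqrt(1/N_num + 1/N_den)} (with a one-count numerator
#' floor when the numerator is zero); the plane-level standard error and
#' relative standard deviation are computed from the per-plane ratio series
#' after dropping planes with zero denominator counts (their number is
#' recorded). ROIs with zero cumulative denominator counts are rejected
#' outright.
#'
#' @param counts Long count table from [extractRoiCounts()].
#' @param instrument \code{"large_geometry"} or \code{"nano"}.
#' @return data.frame (one row per ROI x isotope) with columns
#'   \code{roi_id}, \code{isotope}, \code{N_num}, \code{N_den}, \code{R},
#'   \code{sigma_poisson}, \code{se_planes}, \code{rsd_planes},
#'   \code{n_planes_used}, \code{n_planes_dropped},
#'   \code{rejected_zero_den}, and unset QC flags (see [qcEvaluate()]).
#' @export
computeRatio <- function(counts, instrument = c("large_geometry", "nano")) {
  instrument <- match.arg(instrument)
  sp <- .stack_species(instrument)
  need <- unique(c(sp$den_C, sp$num_C, sp$den_N, sp$num_N))
  missing_sp <- setdiff(need, unique(counts$species))
  if (length(missing_sp))
    stop("input error: count table lacks species ",
         paste(missing_sp, collapse = ", "), " required for ", instrument)
  pivot <- function(species) {
    x <- counts[counts$species == species, ]
    tapply(x$counts, list(roi_id = x$roi_id, plane = x$plane), sum,
           default = 0)
  }
  one_isotope <- function(num_m, den_m, isotope, factor) {
    ids <- as.integer(rownames(num_m))
    N_num <- rowSums(num_m); N_den <- rowSums(den_m)
    R <- ifelse(N_den > 0, factor * N_num / N_den, NA_real_)
    # one-count numerator floor so zero-count ROIs keep a finite error
    Nf <- pmax(N_num, 1)
    sigma <- ifelse(N_den > 0,
                    factor * (Nf / N_den) * sqrt(1 / Nf + 1 / N_den),
                    NA_real_)
    stats_planes <- t(vapply(seq_along(ids), function(i) {
      use <- den_m[i, ] > 0
      n_use <- sum(use)
      if (n_use < 2L) return(c(NA_real_, NA_real_, n_use))
      rp <- factor * num_m[i, use] / den_m[i, use]
      s <- stats::sd(rp); m <- mean(rp)
      rsd <- if (s == 0) 0 else if (m == 0) Inf else 100 * s / abs(m)
      c(s / sqrt(n_use), rsd, n_use)
    }, numeric(3)))
    data.frame(roi_id = ids, isotope = isotope,
               N_num = N_num, N_den = N_den, R = R,
               sigma_poisson = sigma,
               se_planes = stats_planes[, 1],
               rsd_planes = stats_planes[, 2],
               n_planes_used = as.integer(stats_planes[, 3]),
               n_planes_dropped = ncol(den_m) - as.integer(stats_planes[, 3]),
               rejected_zero_den = N_den == 0,
               qc_pass_poisson = NA, qc_pass_rsd = NA, qc_pass = NA)
  }
  den_C <- pivot(sp$den_C); num_C <- pivot(sp$num_C)
  den_N <- if (sp$den_N == sp$den_C) den_C else pivot(sp$den_N)
  num_N <- pivot(sp$num_N)
  rbind(one_isotope(num_C, den_C, "13C", 1 / sp$c_factor),
        one_isotope(num_N, den_N, "15N", 1))
}

#' Apply the counting-statistics quality-control filter
#'
#' Two plane-level criteria are evaluated for every ratio: the plane-level
#' standard error may not exceed \code{max_se_factor} times the Poisson
#' statistics error, and the relative standard deviation across planes may
#' not exceed \code{max_rsd_pct}. Both flags are always recorded. How they
#' combine into the overall \code{qc_pass} is configurable:
#' \describe{
#'   \item{\code{"both"} (default)}{a ratio is rejected only when it
#'     violates both criteria — the conjunction rule. This is the workable
#'     default at realistic count depths: the per-plane RSD of a
#'     minor-isotope ratio is bounded below by counting statistics
#'     (roughly \code{sqrt(n_planes / N_num)}), so at cumulative numerator
#'     counts of a few hundred the RSD criterion alone would reject nearly
#'     every measurement including natural-abundance controls.}
#'   \item{\code{"either"}}{the conservative disjunction: violating either
#'     criterion rejects the ratio.}
#' }
#' ROIs rejected for a zero cumulative denominator fail outright.
#'
#' @param r Ratio table from [computeRatio()].
#' @param max_se_factor Allowed ratio of plane-level SE to Poisson sigma.
#' @param max_rsd_pct Allowed relative standard deviation across planes (%).
#' @param combine How the two criteria combine into \code{qc_pass}.
#' @return \code{r} with \code{qc_pass_poisson}, \code{qc_pass_rsd} and
#'   \code{qc_pass} filled in.
#' @export
qcEvaluate <- function(r, max_se_factor = 2, max_rsd_pct = 25,
                       combine = c("both", "either")) {
  combine <- match.arg(combine)
  r$qc_pass_poisson <- !is.na(r$se_planes) & !is.na(r$sigma_poisson) &
    r$se_planes <= max_se_factor * r$sigma_poisson
  r$qc_pass_rsd <- !is.na(r$rsd_planes) & r$rsd_planes <= max_rsd_pct
  r$qc_pass_poisson[r$rejected_zero_den] <- FALSE
  r$qc_pass_rsd[r$rejected_zero_den] <- FALSE
  r$qc_pass <- if (combine == "either") {
    r$qc_pass_poisson & r$qc_pass_rsd
  } else {
    r$qc_pass_poisson | r$qc_pass_rsd
  }
  r$qc_pass[r$rejected_zero_den] <- FALSE
  r
}

#' Convert between isotope ratio and atom percent
#'
#' \code{toAtomPercent} maps a minor/major isotope ratio R to
#' 100 * R / (1 + R); \code{ratioFromAtomPercent} is its inverse.
#'
#' @param R Isotope ratio (>= 0).
#' @param at_pct Atom percent in [0, 100).
#' @return Numeric vector.
#' @export
toAtomPercent <- function(R) {
  if (any(R < 0, na.rm = TRUE)) stop("input error: negative ratio")
  100 * R / (1 + R)
}

#' @rdname toAtomPercent
#' @export
ratioFromAtomPercent <- function(at_pct) {
  if (any(at_pct < 0 | at_pct >= 100, na.rm = TRUE))
    stop("input error: atom percent outside [0, 100)")
  at_pct / (100 - at_pct)
}

#' Instrument mass-fractionation calibration
#'
#' Estimates one multiplicative correction factor per isotope from
#' QC-passing control ROIs: \code{alpha} is the ratio implied by the bulk
#' (EA-IRMS) reference atom fraction divided by the mean measured control
#' ratio. Applied multiplicatively, it maps the mean control ratio exactly
#' onto the reference.
#'
#' @param controls Ratio table (from [computeRatio()] + [qcEvaluate()])
#'   restricted to control ROIs.
#' @param reference_atom_fraction Named numeric, reference atom fraction
#'   (0-1 scale) per isotope, e.g. \code{c("13C" = 0.011112, "15N" =
#'   0.003663)}.
#' @return data.frame with columns \code{isotope},
#'   \code{reference_atom_fraction}, \code{measured_control_ratio},
#'   \code{alpha}.
#' @export
calibrate <- function(controls, reference_atom_fraction) {
  out <- lapply(unique(controls$isotope), function(iso) {
    cc <- controls[controls$isotope == iso & controls$qc_pass %in% TRUE, ]
    if (nrow(cc) == 0L)
      stop("calibration error: no QC-passing control ROIs for ", iso)
    if (!iso %in% names(reference_atom_fraction))
      stop("calibration error: no reference atom fraction for ", iso)
    ref_frac <- reference_atom_fraction[[iso]]
    ref_ratio <- ref_frac / (1 - ref_frac)
    meas <- mean(cc$R)
    data.frame(isotope = iso, reference_atom_fraction = ref_frac,
               measured_control_ratio = meas, alpha = ref_ratio / meas)
  })
  do.call(rbind, out)
}

#' Apply a calibration to a ratio table
#'
#' Multiplies \code{R} and \code{sigma_poisson} by the per-isotope
#' \code{alpha}.
#'
#' @param r Ratio table.
#' @param calib Output of [calibrate()].
#' @return Corrected ratio table.
#' @export
applyCalibration <- function(r, calib) {
  a <- calib$alpha[match(r$isotope, calib$isotope)]
  if (anyNA(a)) stop("calibration error: missing isotope in calibration")
  r$R <- r$R * a
  r$sigma_poisson <- r$sigma_poisson * a
  r$se_planes <- r$se_planes * a
  r
}

#' Atom-percent excess relative to non-enriched controls
#'
#' APE = sample atom percent minus the mean atom percent of non-enriched
#' control ROIs from the same session. Values may be slightly negative by
#' measurement noise and are retained unclipped.
#'
#' @param at_pct Sample atom percent values.
#' @param control_mean_at_pct Mean atom percent of the control ROIs.
#' @return Numeric vector of APE values.
#' @export
computeApe <- function(at_pct, control_mean_at_pct) {
  if (is.na(control_mean_at_pct))
    stop("missing control mean atom percent")
  at_pct - control_mean_at_pct
}

#' Assemble per-cell isotope measurements
#'
#' Joins the calibrated 13C and 15N ratio rows of every ROI into one cell
#' measurement: atom percent per isotope, atom-percent excess relative to
#' the mean of QC-passing control ROIs, and the combined QC flag (a cell
#' passes when both isotope ratios pass).
#'
#' @param ratios Calibrated, QC-evaluated ratio table.
#' @param control_ids ROI ids of non-enriched control ROIs.
#' @return data.frame with columns \code{roi_id}, \code{at_pct_13C},
#'   \code{at_pct_15N}, \code{ape_13C}, \code{ape_15N}, \code{qc_pass}.
#' @export
cellMeasurements <- function(ratios, control_ids) {
  wide <- function(iso) {
    x <- ratios[ratios$isotope == iso, ]
    data.frame(roi_id = x$roi_id, at_pct = toAtomPercent(x$R),
               qc = x$qc_pass %in% TRUE)
  }
  c13 <- wide("13C"); n15 <- wide("15N")
  m <- merge(c13, n15, by = "roi_id", suffixes = c("_13C", "_15N"))
  ctrl <- m[m$roi_id %in% control_ids & m$qc_13C & m$qc_15N, ]
  if (nrow(ctrl) == 0L) stop("no QC-passing control ROIs for APE baseline")
  data.frame(
    roi_id = m$roi_id,
    at_pct_13C = m$at_pct_13C, at_pct_15N = m$at_pct_15N,
    ape_13C = computeApe(m$at_pct_13C, mean(ctrl$at_pct_13C)),
    ape_15N = computeApe(m$at_pct_15N, mean(ctrl$at_pct_15N)),
    qc_pass = m$qc_13C & m$qc_15N)
}

#' Split bacterium ROIs into associated and free-living
#'
#' Bacteria at least \code{threshold_um} from the nearest host cell are
#' free-living (the boundary is inclusive); closer ones are
#' host-associated. Bacteria without a distance are flagged unclassified.
#'
#' @param rois An [ROISet-class].
#' @param threshold_um Distance threshold in micrometres.
#' @return The [ROISet-class] with an added/updated \code{bacterial_class}
#'   column (\code{associated}, \code{free_living}, \code{unclassified};
#'   NA for non-bacterium ROIs).
#' @export
classifyFreeLiving <- function(rois, threshold_um = 10) {
  info <- roiInfo(rois)
  cls <- rep(NA_character_, nrow(info))
  is_b <- info$category == "bacterium"
  d <- info$min_distance_to_host_cell_um
  cls[is_b] <- ifelse(is.na(d[is_b]), "unclassified",
                      ifelse(d[is_b] >= threshold_um,
                             "free_living", "associated"))
  info$bacterial_class <- cls
  ROISet(mask = roiMask(rois), info = info)
}

#' Quantify one ion-count stack end to end
#'
#' Convenience wrapper: extract ROI counts, compute cumulative-count
#' ratios, and evaluate QC.
#'
#' @inheritParams extractRoiCounts
#' @inheritParams qcEvaluate
#' @return QC-evaluated ratio table.
#' @export
quantifyStack <- function(stack, rois, max_se_factor = 2, max_rsd_pct = 25,
                          combine = "both") {
  counts <- extractRoiCounts(stack, rois)
  qcEvaluate(computeRatio(counts, instrumentMode(stack)),
             max_se_factor = max_se_factor, max_rsd_pct = max_rsd_pct,
             combine = combine)
}
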