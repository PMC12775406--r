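#' Bulk fixation rate from the tracer mass balance
#'
#' rate = (A_PN - A_PN0) / (A_N - A_PN0) * PN / dt, where A_PN and A_PN0
#' are the particulate-pool atom fractions after and before the incubation,
#' A_N the source-pool atom fraction, PN the particulate pool concentration
#' (umol L-1) and dt the incubation duration (d).
#'
#' @param s data.frame with columns \code{a_pn}, \code{a_pn0}, \code{a_n},
#'   \code{pn_umol_l}, \code{dt_days} (one row per bottle), e.g. from
#'   [simulateBulkSamples()].
#' @return Numeric vector of fixation rates (umol L-1 d-1).
#' @export
bulkFixationRate <- function(s) {
  req <- c("a_pn", "a_pn0", "a_n", "pn_umol_l", "dt_days")
  if (!all(req %in% names(s)))
    stop("bulk sample table lacks columns: ",
         paste(setdiff(req, names(s)), collapse = ", "))
  if (any(s$a_n <= s$a_pn0))
    stop("input error: source pool not enriched above the initial ",
         "particulate pool (A_N <= A_PN0)")
  if (any(s$pn_umol_l <= 0) || any(s$dt_days <= 0))
    stop("input error: PN and dt must be > 0")
  (s$a_pn - s$a_pn0) / (s$a_n - s$a_pn0) * s$pn_umol_l / s$dt_days
}

#' Specific assimilation rate from atom-percent excess
#'
#' Linear tracer model (default): k = APE_cell / (APE_source * dt), the
#' standard short-incubation approximation. An exponential form
#' k = ln(1 + APE_cell / (APE_source - APE_cell)) / dt is available for
#' incubations where the cell enrichment approaches the source enrichment.
#'
#' @param ape_cell Cell atom-percent excess.
#' @param ape_source Source-pool atom-percent excess (> 0).
#' @param dt_days Incubation duration in days (> 0).
#' @param model \code{"linear"} or \code{"exponential"}.
#' @return Specific rate k (d-1).
#' @export
specificRate <- function(ape_cell, ape_source, dt_days,
                         model = c("linear", "exponential")) {
  model <- match.arg(model)
  if (any(ape_source <= 0)) stop("input error: ape_source must be > 0")
  if (any(dt_days <= 0)) stop("input error: dt_days must be > 0")
  if (model == "linear") {
    ape_cell / (ape_source * dt_days)
  } else {
    log(1 + ape_cell / (ape_source - ape_cell)) / dt_days
  }
}

#' Per-cell incorporation rate
#'
#' Multiplies a specific rate (d-1) by the cell-type elemental content
#' (pmol cell-1) to obtain a net incorporation rate (pmol cell-1 d-1).
#'
#' @param k Specific rate (d-1).
#' @param params Output of [cellTypeParams()].
#' @param category ROI category (must have contents in \code{params}).
#' @param element \code{"C"} or \code{"N"}.
#' @return Rate in pmol cell-1 d-1.
#' @export
cellRate <- function(k, params, category, element = c("C", "N")) {
  element <- match.arg(element)
  i <- match(category, params$category)
  if (anyNA(i))
    stop("input error: no cell contents for category ",
         paste(unique(category[is.na(i)]), collapse = ", "))
  content <- if (element == "C") params$C_content[i] else params$N_content[i]
  k * content
}

#' Molar C:N incorporation ratio
#'
#' @param r_C,r_N Carbon and nitrogen incorporation rates (same units).
#' @return r_C / r_N; NA (flagged undefined) where r_N <= 0.
#' @export
cnRatio <- function(r_C, r_N) {
  out <- ifelse(r_N > 0, r_C / r_N, NA_real_)
  if (any(!(r_N > 0), na.rm = TRUE))
    attr(out, "undefined") <- which(!(r_N > 0))
  out
}

#' Single-cell rates for a measured population
#'
#' Applies the tracer model to every QC-passing host-cell measurement:
#' specific C and N assimilation rates from the 13C/15N atom-percent
#' excess, per-cell incorporation rates via the cell-type contents, and the
#' molar C:N incorporation ratio.
#'
#' @param cells Cell-measurement table from [cellMeasurements()].
#' @param rois The matching [ROISet-class] (for category and infection
#'   status).
#' @param params [cellTypeParams()].
#' @param labeling Source enrichments \code{c(apeC=, apeN=)} (at% excess).
#' @param dt_days Incubation duration (d).
#' @param model Tracer model passed to [specificRate()].
#' @return data.frame with columns \code{roi_id}, \code{category},
#'   \code{infection_status}, \code{k_C}, \code{k_N}, \code{r_C},
#'   \code{r_N}, \code{cn_ratio}.
#' @export
cellRates <- function(cells, rois, params = cellTypeParams(),
                      labeling = c(apeC = 3.9, apeN = 0.67),
                      dt_days = 0.875, model = "linear") {
  info <- roiInfo(rois)
  m <- merge(cells[cells$qc_pass, ], info[, c("roi_id", "category",
                                              "infection_status")],
             by = "roi_id")
  m <- m[m$category %in% .HOST_CATEGORIES, ]
  k_C <- specificRate(m$ape_13C, labeling[["apeC"]], dt_days, model)
  k_N <- specificRate(m$ape_15N, labeling[["apeN"]], dt_days, model)
  r_C <- cellRate(k_C, params, m$category, "C")
  r_N <- cellRate(k_N, params, m$category, "N")
  data.frame(roi_id = m$roi_id, category = m$category,
             infection_status = m$infection_status,
             k_C = k_C, k_N = k_N, r_C = r_C, r_N = r_N,
             cn_ratio = as.numeric(cnRatio(r_C, r_N)))
}

#' Group summaries and infected vs non-infected contrasts
#'
#' Summarizes a rate (or any per-cell value) by category x infection
#' status, and derives, per category with both groups present, the percent
#' change (rounded to the nearest integer percent) and absolute difference
#' of the infected relative to the non-infected mean.
#'
#' @param rates data.frame with columns \code{category},
#'   \code{infection_status} and the value column.
#' @param value Name of the value column (e.g. \code{"r_N"}).
#' @return List with \code{groups} (category, status, n, mean, sd) and
#'   \code{contrasts} (category, mean_non_infected, mean_infected,
#'   pct_change, abs_difference).
#' @export
summarizeGroups <- function(rates, value = "r_N") {
  if (!value %in% names(rates)) stop("no column ", value)
  v <- rates[[value]]
  keep <- !is.na(v) & !is.na(rates$infection_status)
  rates <- rates[keep, ]; v <- v[keep]
  if (nrow(rates) == 0L) stop("no cells to summarize")
  key <- interaction(rates$category, rates$infection_status, drop = TRUE)
  groups <- do.call(rbind, lapply(levels(key), function(k) {
    sel <- key == k
    data.frame(category = rates$category[sel][1],
               status = rates$infection_status[sel][1],
               n = sum(sel), mean = mean(v[sel]), sd = stats::sd(v[sel]))
  }))
  contrasts <- NULL
  for (cat in unique(groups$category)) {
    g <- groups[groups$category == cat, ]
    ni <- g[g$status == "non_infected", ]; inf <- g[g$status == "infected", ]
    if (nrow(ni) == 1L && nrow(inf) == 1L) {
      contrasts <- rbind(contrasts, data.frame(
        category = cat,
        mean_non_infected = ni$mean, mean_infected = inf$mean,
        pct_change = round(100 * (ni$mean - inf$mean) / ni$mean),
        abs_difference = ni$mean - inf$mean))
    }
  }
  missing_groups <- setdiff(
    unique(rates$category),
    groups$category[duplicated(groups$category)])
  if (length(missing_groups))
    warning("categories without both infection groups omitted from ",
            "contrasts: ", paste(missing_groups, collapse = ", "))
  list(groups = groups, contrasts = contrasts)
}
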