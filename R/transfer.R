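#' Pair sporangia with their host cells
#'
#' Builds one row per (sporangium, linked host cell), so a junction
#' sporangium whose host_link names both the akinete and the heterocyte
#' yields two rows sharing the sporangium ROI. Pairs are restricted to
#' QC-passing members on both sides; sporangia with dangling host links are
#' excluded with a warning. Per-pair APE ratios are attached via
#' [apeRatio()].
#'
#' @param rois An [ROISet-class].
#' @param cells Cell-measurement table from [cellMeasurements()].
#' @return data.frame with columns \code{sporangium_roi}, \code{host_roi},
#'   \code{host_category}, \code{sporangial_stage}, APE columns for both
#'   members, and \code{ratio_13C}, \code{ratio_15N}. Attribute
#'   \code{n_dropped} counts pairs lost to QC failure or dangling links.
#' @export
pairHostSporangium <- function(rois, cells) {
  info <- roiInfo(rois)
  sp <- info[info$category == "sporangium", , drop = FALSE]
  meas <- cells[cells$qc_pass, ]
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(sp))) {
    hosts <- .parse_host_link(sp$host_link[i])
    if (length(hosts) == 0L) {
      warning("sporangium ", sp$roi_id[i], " has no resolvable host link")
      dropped <- dropped + 1L
      next
    }
    sm <- meas[meas$roi_id == sp$roi_id[i], ]
    for (h in hosts) {
      hm <- meas[meas$roi_id == h, ]
      hcat <- info$category[match(h, info$roi_id)]
      if (is.na(hcat)) {
        warning("sporangium ", sp$roi_id[i], " links to unknown ROI ", h)
        dropped <- dropped + 1L
        next
      }
      if (nrow(sm) == 0L || nrow(hm) == 0L) {
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sporangium_roi = sp$roi_id[i], host_roi = h, host_category = hcat,
        sporangial_stage = sp$sporangial_stage[i],
        ape_13C_sporangium = sm$ape_13C, ape_15N_sporangium = sm$ape_15N,
        ape_13C_host = hm$ape_13C, ape_15N_host = hm$ape_15N)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sporangium_roi = integer(), host_roi = integer(),
               host_category = character(), sporangial_stage = character(),
               ape_13C_sporangium = numeric(), ape_15N_sporangium = numeric(),
               ape_13C_host = numeric(), ape_15N_host = numeric())
  pairs <- apeRatio(pairs)
  attr(pairs, "n_dropped") <- dropped
  pairs
}

#' Per-pair sporangium/host APE ratios
#'
#' ratio = APE_sporangium / APE_host per isotope; undefined (NA) where the
#' host APE is not positive — such pairs are excluded from ratio means but
#' retained for APE-level comparisons.
#'
#' @param pairs Pair table from [pairHostSporangium()] (ratio columns are
#'   (re)computed).
#' @return The pair table with \code{ratio_13C} and \code{ratio_15N}.
#' @export
apeRatio <- function(pairs) {
  pairs$ratio_13C <- ifelse(pairs$ape_13C_host > 0,
                            pairs$ape_13C_sporangium / pairs$ape_13C_host,
                            NA_real_)
  pairs$ratio_15N <- ifelse(pairs$ape_15N_host > 0,
                            pairs$ape_15N_sporangium / pairs$ape_15N_host,
                            NA_real_)
  pairs
}

#' Fold changes between group-mean enrichments
#'
#' Computes, for every ordered pair of groups, the ratio of group-mean APEs
#' per isotope and the minimum across isotopes (the quantity behind
#' "at least x-fold" statements). Note this is deliberately distinct from
#' the mean of per-pair ratios reported by [originSlope()]: ratios of group
#' means and means of pairwise ratios differ.
#'
#' @param group_means data.frame with columns \code{group}, \code{ape_13C},
#'   \code{ape_15N} (group-mean APEs).
#' @return data.frame with \code{numerator}, \code{denominator},
#'   \code{fold_13C}, \code{fold_15N}, \code{fold_min}.
#' @export
groupFoldChanges <- function(group_means) {
  g <- group_means
  out <- NULL
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    if (i == j) next
    f13 <- if (g$ape_13C[j] > 0) g$ape_13C[i] / g$ape_13C[j] else NA_real_
    f15 <- if (g$ape_15N[j] > 0) g$ape_15N[i] / g$ape_15N[j] else NA_real_
    out <- rbind(out, data.frame(
      numerator = g$group[i], denominator = g$group[j],
      fold_13C = f13, fold_15N = f15,
      fold_min = suppressWarnings(min(f13, f15, na.rm = TRUE))))
  }
  out
}

#' Origin-constrained trend-line slope
#'
#' The trend line through the origin whose slope equals the group mean of
#' the per-pair APE ratios (y = mean ratio x host APE, intercept fixed at
#' the origin) — the stated construction, not a least-squares fit.
#'
#' @param pairs Pair table from [pairHostSporangium()].
#' @return data.frame with \code{host_category}, \code{isotope},
#'   \code{slope}, \code{n_pairs}, \code{n_undefined}.
#' @export
originSlope <- function(pairs) {
  out <- NULL
  for (cat in unique(pairs$host_category)) {
    p <- pairs[pairs$host_category == cat, ]
    for (iso in c("13C", "15N")) {
      r <- p[[paste0("ratio_", iso)]]
      valid <- !is.na(r)
      if (sum(valid) == 0L)
        stop("no valid pairs for ", cat, " / ", iso)
      out <- rbind(out, data.frame(
        host_category = cat, isotope = iso, slope = mean(r[valid]),
        n_pairs = sum(valid), n_undefined = sum(!valid)))
    }
  }
  out
}

# ---- zero-inflated count models ------------------------------------------

# negative log-likelihood on a count frequency table; groups enter the
# count component through a log-link coefficient, zero inflation is
# intercept-only
.zi_negll <- function(par, vals, freqs, grp, family) {
  pi <- stats::plogis(par[1])
  has_grp <- length(unique(grp)) > 1L
  k <- if (family == "zinb") exp(par[length(par)]) else Inf
  ll <- 0
  for (g in unique(grp)) {
    sel <- grp == g
    mu <- exp(par[2] + if (has_grp && g == unique(grp)[2]) par[3] else 0)
    d0 <- if (family == "zinb") stats::dnbinom(vals[sel], size = k, mu = mu)
          else stats::dpois(vals[sel], mu)
    p <- ifelse(vals[sel] == 0, pi + (1 - pi) * d0, (1 - pi) * d0)
    ll <- ll + sum(freqs[sel] * log(pmax(p, 1e-300)))
  }
  -ll
}

.zi_freq <- function(counts, group) {
  if (is.null(group)) group <- rep("g1", length(counts))
  group <- as.character(group)
  lv <- unique(group)
  out <- NULL
  for (g in lv) {
    tab <- table(counts[group == g])
    out <- rbind(out, data.frame(val = as.integer(names(tab)),
                                 freq = as.integer(tab), grp = g))
  }
  list(vals = out$val, freqs = out$freq, grp = out$grp, levels = lv)
}

.zi_fit_one <- function(fr, family, start) {
  fit <- stats::optim(start, .zi_negll, vals = fr$vals, freqs = fr$freqs,
                      grp = fr$grp, family = family, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  se <- rep(NA_real_, length(fit$par))
  ok <- fit$convergence == 0
  h <- try(solve(fit$hessian), silent = TRUE)
  if (!inherits(h, "try-error") && all(diag(h) > 0))
    se <- sqrt(diag(h))
  list(par = fit$par, se = se, loglik = -fit$value,
       converged = ok,
       aic = 2 * length(fit$par) + 2 * fit$value)
}

#' Fit zero-inflated count models to colonization counts
#'
#' Maximum-likelihood fits of a zero-inflated Poisson (ZIP) and a
#' zero-inflated negative binomial (ZINB) to bacterial colonization counts,
#' with an optional two-level group entering the count component through a
#' log link (the zero-inflation probability is intercept-only). The model
#' with the lower AIC is selected. The count-component rate ratio between
#' the two groups is reported with a profile-likelihood confidence
#' interval (Wald fallback).
#'
#' @param counts Non-negative integer vector.
#' @param group Optional two-level grouping (factor/character); the rate
#'   ratio is second level vs first.
#' @param conf_level Confidence level for the rate-ratio interval.
#' @return List of class \code{"zinbFit"}: \code{model}, \code{pi},
#'   \code{mu} (count-component mean of the reference group), \code{k}
#'   (NA for ZIP), \code{loglik}, \code{aic}, \code{aic_zip},
#'   \code{aic_zinb}, \code{converged}, \code{rate_ratio},
#'   \code{rate_ratio_ci}, \code{coef}, \code{se}.
#' @export
zinbFit <- function(counts, group = NULL, conf_level = 0.95) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!is.null(group) && length(unique(group)) != 2L)
    stop("group must have exactly two levels")
  if (all(counts == 0)) {
    # boundary: all mass on the structural-zero component
    return(structure(list(model = "zip", pi = 1, mu = NA_real_,
                          k = NA_real_, loglik = 0, aic = 2 * 2,
                          aic_zip = 4, aic_zinb = 6, converged = TRUE,
                          boundary = TRUE, rate_ratio = NA_real_,
                          rate_ratio_ci = c(NA_real_, NA_real_),
                          coef = NULL, se = NULL), class = "zinbFit"))
  }
  fr <- .zi_freq(counts, group)
  has_grp <- length(fr$levels) > 1L
  p0 <- mean(counts == 0)
  mu0 <- max(mean(counts[counts > 0]), 0.1)
  start_zip <- c(stats::qlogis(max(min(p0, 0.95), 0.05)), log(mu0))
  if (has_grp) start_zip <- c(start_zip, 0)
  start_zinb <- c(start_zip, 0)
  fit_zip <- .zi_fit_one(fr, "zip", start_zip)
  fit_zinb <- .zi_fit_one(fr, "zinb", start_zinb)
  use_zinb <- fit_zinb$aic < fit_zip$aic
  fit <- if (use_zinb) fit_zinb else fit_zip
  family <- if (use_zinb) "zinb" else "zip"
  beta_i <- if (has_grp) 3L else NA_integer_
  rr <- rr_ci <- c(NA_real_, NA_real_)
  if (has_grp) {
    rr <- exp(fit$par[beta_i])
    rr_ci <- .zi_profile_ci(fr, family, fit, beta_i, conf_level)
  }
  structure(list(
    model = family,
    pi = stats::plogis(fit$par[1]),
    mu = exp(fit$par[2]),
    k = if (use_zinb) exp(fit$par[length(fit$par)]) else NA_real_,
    loglik = fit$loglik, aic = fit$aic,
    aic_zip = fit_zip$aic, aic_zinb = fit_zinb$aic,
    converged = fit$converged, boundary = FALSE,
    rate_ratio = if (has_grp) rr else NA_real_,
    rate_ratio_ci = rr_ci,
    coef = fit$par, se = fit$se), class = "zinbFit")
}

# profile-likelihood CI for the group coefficient; Wald fallback
.zi_profile_ci <- function(fr, family, fit, beta_i, conf_level) {
  crit <- stats::qchisq(conf_level, 1) / 2
  llmax <- fit$loglik
  pl <- function(b) {
    start <- fit$par[-beta_i]
    nll <- function(p) {
      full <- append(p, b, after = beta_i - 1L)
      .zi_negll(full, fr$vals, fr$freqs, fr$grp, family)
    }
    -stats::optim(start, nll, method = "BFGS",
                  control = list(maxit = 300))$value
  }
  b_hat <- fit$par[beta_i]
  se <- fit$se[beta_i]
  wald <- exp(b_hat + c(-1, 1) * stats::qnorm(1 - (1 - conf_level) / 2) *
              (if (is.na(se)) 0 else se))
  if (is.na(se) || se == 0) return(wald)
  f <- function(b) llmax - pl(b) - crit
  lo <- try(stats::uniroot(f, c(b_hat - 6 * se, b_hat), tol = 1e-4)$root,
            silent = TRUE)
  hi <- try(stats::uniroot(f, c(b_hat, b_hat + 6 * se), tol = 1e-4)$root,
            silent = TRUE)
  if (inherits(lo, "try-error") || inherits(hi, "try-error")) return(wald)
  exp(c(lo, hi))
}

#' @export
print.zinbFit <- function(x, ...) {
  cat("Zero-inflated count model (selected: ", toupper(x$model), ")\n",
      sep = "")
  cat(sprintf("  pi = %.3f, mu = %.3f, k = %s\n", x$pi, x$mu,
              ifelse(is.na(x$k), "-", sprintf("%.3f", x$k))))
  cat(sprintf("  logLik = %.2f, AIC(zip) = %.1f, AIC(zinb) = %.1f\n",
              x$loglik, x$aic_zip, x$aic_zinb))
  if (!is.na(x$rate_ratio))
    cat(sprintf("  rate ratio = %.3f (CI %.3f-%.3f)\n", x$rate_ratio,
                x$rate_ratio_ci[1], x$rate_ratio_ci[2]))
  invisible(x)
}
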