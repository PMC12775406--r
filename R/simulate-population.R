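#' Simulate a Dolichospermum-like population with fungal infections
#'
#' Draws filaments (cell chains of at least four cells), assigns
#' differentiated cell types (vegetative cells, heterocytes, akinetes; type
#' I/II from akinete-heterocyte adjacency), infections per cell type,
#' sporangium ROIs (merged to a single junction sporangium when both members
#' of an akinete-heterocyte junction are infected), host-associated and
#' free-living bacteria, and non-enriched control ROIs, together with a
#' ground-truth table of true enrichments and incorporation rates.
#'
#' Filament lengths are drawn from lognormal distributions re-parameterized
#' to the configured means/SDs (lengths are positive and right-skewed).
#' Infections are restricted to an "infected-class" subset of filaments;
#' per-type infection probabilities are scaled internally so that the
#' marginal per-type prevalences match \code{cfg$prevalence_by_type}.
#'
#' @param cfg A [populationConfig()].
#' @return List with elements \code{rois} (an [ROISet-class]; the mask is
#'   empty at population level, use [rasterizeRois()] to lay ROIs out on a
#'   raster) and \code{truth} (the ground-truth data.frame, one row per ROI).
#' @export
simulatePopulation <- function(cfg) {
  stopifnot(inherits(cfg, "PopulationConfig"))
  withSeed(deriveSeed(cfg$seed, "population"), {
    comp <- cfg$composition
    prev <- cfg$prevalence_by_type
    pf <- cfg$filament_infected_frac
    Li <- cfg$filament_length_um$infected[["mean"]]
    Ln <- cfg$filament_length_um$non_infected[["mean"]]
    # expected fraction of cells sitting in infected-class filaments
    w <- if (pf > 0) pf * Li / (pf * Li + (1 - pf) * Ln) else 0
    # class-specific akinete fractions preserving the configured marginal
    a <- comp[["akinete"]]; h <- comp[["heterocyte"]]
    beta <- cfg$akinete_infected_bias
    a_non <- if (w > 0) a / (w * beta + (1 - w)) else a
    a_inf <- beta * a_non
    comp_class <- list(
      infected = c(vegetative = 1 - h - a_inf, heterocyte = h, akinete = a_inf),
      non_infected = c(vegetative = 1 - h - a_non, heterocyte = h,
                       akinete = a_non))
    # P(filament class = infected | cell type)
    marg_veg <- w * comp_class$infected[["vegetative"]] +
      (1 - w) * comp_class$non_infected[["vegetative"]]
    p_class <- c(vegetative = if (marg_veg > 0)
                   w * comp_class$infected[["vegetative"]] / marg_veg else 0,
                 heterocyte = w,
                 akinete = if (a > 0) w * a_inf / a else 0)
    q <- vapply(names(prev), function(t) {
      if (prev[[t]] == 0) return(0)
      if (p_class[[t]] == 0) return(0)
      qq <- prev[[t]] / p_class[[t]]
      if (qq > 1) {
        warning("prevalence for ", t, " not reachable given filament ",
                "structure; capping conditional infection probability at 1")
        qq <- 1
      }
      qq
    }, numeric(1))

    lnp <- lapply(cfg$filament_length_um, function(p)
      lognormalParams(p[["mean"]], p[["sd"]]))

    cells <- list(); n_done <- 0L; fil_id <- 0L
    while (n_done < cfg$n_cells) {
      fil_id <- fil_id + 1L
      infected_class <- stats::runif(1) < pf
      pars <- if (infected_class) lnp$infected else lnp$non_infected
      len <- stats::rlnorm(1, pars[["meanlog"]], pars[["sdlog"]])
      n_f <- max(4L, as.integer(round(len / cfg$cell_length_um)))
      cc <- if (infected_class) comp_class$infected else comp_class$non_infected
      type <- sample(names(cc), n_f, replace = TRUE, prob = cc)
      # akinetes differentiate preferentially next to heterocytes, which is
      # what makes akinete-heterocyte junctions (type I cells) common
      aki_pos <- which(type == "akinete")
      het_pos <- which(type == "heterocyte")
      if (length(aki_pos) && length(het_pos)) {
        for (ap in aki_pos) {
          if (stats::runif(1) >= cfg$junction_affinity) next
          nbrs <- unique(pmin(pmax(c(het_pos - 1L, het_pos + 1L), 1L), n_f))
          nbrs <- nbrs[type[nbrs] == "vegetative"]
          if (!length(nbrs)) next
          tgt <- if (length(nbrs) == 1L) nbrs else sample(nbrs, 1L)
          type[c(ap, tgt)] <- type[c(tgt, ap)]
        }
        het_pos <- which(type == "heterocyte")
      }
      # type I = member of an akinete-heterocyte junction
      left <- c(NA, type[-n_f]); right <- c(type[-1], NA)
      cat_full <- ifelse(
        type == "heterocyte",
        ifelse(left %in% "akinete" | right %in% "akinete",
               "heterocyte_I", "heterocyte_II"),
        ifelse(type == "akinete",
               ifelse(left %in% "heterocyte" | right %in% "heterocyte",
                      "akinete_I", "akinete_II"),
               "vegetative"))
      inf <- if (infected_class) stats::runif(n_f) < q[type] else rep(FALSE, n_f)
      cells[[fil_id]] <- data.frame(
        filament_id = fil_id, pos = seq_len(n_f), cell_type = type,
        category = cat_full, infected = inf,
        length_um = len, infected_class = infected_class)
      n_done <- n_done + n_f
    }
    cells <- do.call(rbind, cells)
    cells$roi_id <- seq_len(nrow(cells))

    # sporangium placement: merge infected akinete-heterocyte junction pairs
    spor <- list()
    consumed <- rep(FALSE, nrow(cells))
    for (f in unique(cells$filament_id)) {
      idx <- which(cells$filament_id == f)
      for (i in idx) {
        if (!cells$infected[i] || consumed[i]) next
        partner <- NA_integer_
        for (j in c(i - 1L, i + 1L)) {
          if (j %in% idx && cells$infected[j] && !consumed[j] &&
              ((cells$cell_type[i] == "akinete" &&
                cells$cell_type[j] == "heterocyte") ||
               (cells$cell_type[i] == "heterocyte" &&
                cells$cell_type[j] == "akinete"))) {
            partner <- j; break
          }
        }
        consumed[i] <- TRUE
        if (!is.na(partner)) {
          consumed[partner] <- TRUE
          spor[[length(spor) + 1L]] <- list(
            host_link = paste(cells$roi_id[c(i, partner)], collapse = ";"),
            host_context = "akihet", filament_id = f,
            x = mean(cells$pos[c(i, partner)]))
        } else {
          ctx <- switch(cells$category[i],
                        vegetative = "vegetative",
                        heterocyte_II = "heterocyte_II",
                        akinete_II = "akinete_II",
                        "akihet")
          spor[[length(spor) + 1L]] <- list(
            host_link = as.character(cells$roi_id[i]),
            host_context = ctx, filament_id = f, x = cells$pos[i])
        }
      }
    }

    cell_info <- data.frame(
      roi_id = cells$roi_id, category = cells$category,
      sporangial_stage = "none",
      host_link = NA_character_, filament_id = cells$filament_id,
      centroid_x_um = cells$pos * cfg$cell_length_um,
      centroid_y_um = cells$filament_id * 10,
      min_distance_to_host_cell_um = 0,
      infection_status = ifelse(cells$infected, "infected", "non_infected"))

    next_id <- nrow(cells)
    spor_info <- NULL
    if (length(spor)) {
      spor_info <- data.frame(
        roi_id = next_id + seq_along(spor),
        category = "sporangium",
        sporangial_stage = sample(names(cfg$sporangial_stage_probs),
                                  length(spor), replace = TRUE,
                                  prob = cfg$sporangial_stage_probs),
        host_link = vapply(spor, `[[`, "", "host_link"),
        filament_id = vapply(spor, `[[`, 0, "filament_id"),
        centroid_x_um = vapply(spor, `[[`, 0, "x") * cfg$cell_length_um,
        centroid_y_um = vapply(spor, `[[`, 0, "filament_id") * 10 + 3,
        min_distance_to_host_cell_um = 0,
        infection_status = NA_character_)
      next_id <- next_id + length(spor)
    }

    # host-associated bacteria: zero-inflated negative binomial per cell
    bz <- cfg$bacteria_zinb
    nb <- ifelse(cells$infected,
                 simulateBacteriaCounts(nrow(cells),
                                        bz$infected[["pi"]],
                                        bz$infected[["mu"]],
                                        bz$infected[["k"]]),
                 simulateBacteriaCounts(nrow(cells),
                                        bz$non_infected[["pi"]],
                                        bz$non_infected[["mu"]],
                                        bz$non_infected[["k"]]))
    host_of_bact <- rep(cells$roi_id, nb)
    bact_info <- NULL
    if (length(host_of_bact)) {
      bi <- match(host_of_bact, cells$roi_id)
      bact_info <- data.frame(
        roi_id = next_id + seq_along(host_of_bact),
        category = "bacterium", sporangial_stage = "none",
        host_link = as.character(host_of_bact),
        filament_id = cells$filament_id[bi],
        centroid_x_um = cells$pos[bi] * cfg$cell_length_um +
          stats::runif(length(bi), -2, 2),
        centroid_y_um = cells$filament_id[bi] * 10 - 3,
        min_distance_to_host_cell_um = stats::runif(length(bi), 0.2, 8),
        infection_status = NA_character_)
      next_id <- next_id + length(host_of_bact)
    }
    free_info <- NULL
    if (cfg$n_free_bacteria > 0) {
      free_info <- data.frame(
        roi_id = next_id + seq_len(cfg$n_free_bacteria),
        category = "bacterium", sporangial_stage = "none",
        host_link = NA_character_, filament_id = NA_integer_,
        centroid_x_um = stats::runif(cfg$n_free_bacteria, 0, 500),
        centroid_y_um = -20,
        min_distance_to_host_cell_um = stats::runif(cfg$n_free_bacteria,
                                                    10, 60),
        infection_status = NA_character_)
      next_id <- next_id + cfg$n_free_bacteria
    }
    ctrl_info <- NULL
    if (cfg$n_control > 0) {
      ctrl_info <- data.frame(
        roi_id = next_id + seq_len(cfg$n_control),
        category = "control", sporangial_stage = "none",
        host_link = NA_character_, filament_id = NA_integer_,
        centroid_x_um = stats::runif(cfg$n_control, 0, 500),
        centroid_y_um = -40,
        min_distance_to_host_cell_um = NA_real_,
        infection_status = NA_character_)
    }
    info <- rbind(cell_info, spor_info, bact_info, free_info, ctrl_info)

    # ground truth: enrichment group, true APEs, true specific and
    # per-cell rates
    host_ctx <- rep(NA_character_, nrow(info))
    if (length(spor))
      host_ctx[info$category == "sporangium"] <-
        vapply(spor, `[[`, "", "host_context")
    host_ctx[info$category == "bacterium"] <-
      ifelse(is.na(info$host_link[info$category == "bacterium"]),
             "free_living", "associated")
    group <- vapply(seq_len(nrow(info)), function(i) {
      ctx <- host_ctx[i]
      if (info$category[i] == "sporangium" && ctx != "vegetative" &&
          !ctx %in% c("heterocyte_II", "akinete_II")) ctx <- "akihet"
      enrichmentGroup(info$category[i], info$infection_status[i], ctx)
    }, character(1))
    en <- cfg$true_enrichment[match(group, cfg$true_enrichment$group), ]
    if (anyNA(en$group))
      stop("true_enrichment table lacks groups: ",
           paste(unique(group[is.na(en$group)]), collapse = ", "))
    ape13 <- rEnrichment(nrow(info), en$ape13C_mean, en$ape13C_sd)
    ape15 <- rEnrichment(nrow(info), en$ape15N_mean, en$ape15N_sd)
    kC <- ape13 / (cfg$labeling[["apeC"]] * cfg$dt_days)
    kN <- ape15 / (cfg$labeling[["apeN"]] * cfg$dt_days)
    cm <- match(info$category, cfg$cell_contents$category)
    rC <- kC * cfg$cell_contents$C_content[cm]
    rN <- kN * cfg$cell_contents$N_content[cm]
    truth <- data.frame(
      roi_id = info$roi_id, group = group, category = info$category,
      infection_status = info$infection_status,
      host_link = info$host_link,
      true_ape13C = ape13, true_ape15N = ape15,
      true_kC = kC, true_kN = kN, true_rC = rC, true_rN = rN)

    list(rois = ROISet(mask = matrix(0L, 1, 1), info = info), truth = truth)
  })
}

#' Draw true enrichment values for simulated ROIs
#'
#' Enrichments are positive and right-skewed, so they are drawn from
#' lognormal distributions re-parameterized to the requested mean and SD
#' (the draws are unbiased for the group mean, unlike a Gaussian truncated
#' at zero). A zero mean or zero SD degenerates to the constant.
#'
#' @param n Number of draws.
#' @param mean,sd Target means and SDs (vectorized, atom percent excess).
#' @return Numeric vector of non-negative enrichments.
#' @export
rEnrichment <- function(n, mean, sd) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  out <- mean
  pos <- mean > 0 & sd > 0
  if (any(pos)) {
    sdlog2 <- log(1 + (sd[pos] / mean[pos])^2)
    out[pos] <- stats::rlnorm(sum(pos),
                              log(mean[pos]) - sdlog2 / 2,
                              sqrt(sdlog2))
  }
  out
}

#' Draw zero-inflated negative binomial colonization counts
#'
#' Independent ZINB draws: with probability \code{pi} a structural zero,
#' otherwise a negative binomial count with mean \code{mu} and dispersion
#' \code{k} (variance \code{mu + mu^2/k}).
#'
#' @param n Number of draws.
#' @param pi Zero-inflation probability in \code{[0, 1]}.
#' @param mu Mean of the count component (> 0).
#' @param k Dispersion (size) of the count component (> 0).
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return Integer vector of length \code{n}.
#' @export
simulateBacteriaCounts <- function(n, pi, mu, k, seed = NULL) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  if (mu <= 0) stop("mu must be > 0")
  if (k <= 0) stop("k must be > 0")
  draw <- function() {
    zero <- stats::runif(n) < pi
    y <- stats::rnbinom(n, size = k, mu = mu)
    as.integer(ifelse(zero, 0L, y))
  }
  if (is.null(seed)) draw() else withSeed(deriveSeed(seed, "bacteria"), draw())
}
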