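# shared fixtures and independent oracles

# direct zero-inflated log-likelihood, used as the grid-search oracle for
# the optimizing fitter (kept independent of the package internals)
oracle_zi_loglik <- function(counts, pi, mu, k = Inf) {
  tab <- table(counts)
  vals <- as.integer(names(tab)); freq <- as.integer(tab)
  d0 <- if (is.finite(k)) dnbinom(vals, size = k, mu = mu)
        else dpois(vals, mu)
  p <- ifelse(vals == 0, pi + (1 - pi) * d0, (1 - pi) * d0)
  sum(freq * log(pmax(p, 1e-300)))
}

# brute-force per-pixel, per-plane ratio oracle: cumulative numerator and
# denominator sums in exact integer arithmetic
oracle_roi_ratio <- function(stack, mask, roi_id, num_species, den_species,
                             factor = 1) {
  num <- ionCounts(stack, num_species)
  den <- ionCounts(stack, den_species)
  np <- dim(num)[1]
  n_sum <- 0L; d_sum <- 0L
  for (p in seq_len(np)) {
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j] == roi_id) {
        n_sum <- n_sum + num[p, i, j]
        d_sum <- d_sum + den[p, i, j]
      }
    }
  }
  list(num = n_sum, den = d_sum, R = factor * n_sum / d_sum)
}

# tiny hand-built ROISet: one filament of given categories, optionally
# with sporangia and extra ROIs
make_roiset <- function(categories, infected = rep(FALSE, length(categories)),
                        mask = matrix(0L, 1, 1), extra = NULL) {
  n <- length(categories)
  info <- data.frame(
    roi_id = seq_len(n), category = categories,
    sporangial_stage = "none", host_link = NA_character_,
    filament_id = 1L, centroid_x_um = seq_len(n) * 5,
    centroid_y_um = 10, min_distance_to_host_cell_um = 0,
    infection_status = ifelse(infected, "infected", "non_infected"))
  if (!is.null(extra)) info <- rbind(info, extra)
  ROISet(mask = mask, info = info)
}

# long count table for computeRatio from per-plane vectors
make_count_table <- function(..., planes = NULL) {
  species <- list(...)
  np <- length(species[[1]])
  do.call(rbind, lapply(names(species), function(sp)
    data.frame(roi_id = 1L, species = sp, plane = seq_len(np),
               counts = species[[sp]])))
}

# host-cell enrichment groups used across tests (printed group means/SDs)
printed_groups <- function() {
  data.frame(
    group = c("sporangium_akihet", "sporangium_veg", "bacterium_associated",
              "bacterium_free", "akinete_I_non_infected",
              "akinete_I_infected", "vegetative_non_infected",
              "heterocyte_I_non_infected"),
    ape13C_mean = c(1.42, 0.32, 0.59, 0.18, 0.384, 0.273, 0.333, 0.0853),
    ape13C_sd   = c(0.33, 0.33, 0.42, 0.11, 0.094, 0.102, 0.068, 0.043),
    ape15N_mean = c(0.25, 0.02, 0.08, 0.043, 0.0671, 0.0293, 0.0378, 0.017),
    ape15N_sd   = c(0.10, 0.01, 0.07, 0.018, 0.0425, 0.0199, 0.0189, 0.0104))
}

# flat ROI population with fixed per-group truth for recovery experiments:
# n_per_group ROIs per printed group plus n_control control ROIs
make_recovery_population <- function(n_per_group = 125, n_control = 100,
                                     seed = 421) {
  gr <- printed_groups()
  n <- nrow(gr) * n_per_group + n_control
  group <- c(rep(gr$group, each = n_per_group), rep("control", n_control))
  category <- rep("control", n)
  category[grepl("sporangium", group)] <- "sporangium"
  category[grepl("bacterium", group)] <- "bacterium"
  category[grepl("akinete", group)] <- "akinete_I"
  category[grepl("vegetative", group)] <- "vegetative"
  category[grepl("heterocyte", group)] <- "heterocyte_I"
  status <- rep(NA_character_, n)
  status[grepl("non_infected", group)] <- "non_infected"
  status[grepl("_infected", group) & !grepl("non_infected", group)] <- "infected"
  info <- data.frame(
    roi_id = seq_len(n), category = category, sporangial_stage = "none",
    host_link = ifelse(category == "sporangium", "1", NA_character_),
    filament_id = NA_integer_, centroid_x_um = 0, centroid_y_um = 0,
    min_distance_to_host_cell_um = ifelse(category == "bacterium",
                                          ifelse(group == "bacterium_free",
                                                 20, 2), 0),
    infection_status = status)
  gi <- match(group, gr$group)
  m13 <- gr$ape13C_mean[gi]; s13 <- gr$ape13C_sd[gi]
  m15 <- gr$ape15N_mean[gi]; s15 <- gr$ape15N_sd[gi]
  m13[is.na(m13)] <- 0; s13[is.na(s13)] <- 0
  m15[is.na(m15)] <- 0; s15[is.na(s15)] <- 0
  set.seed(seed)
  ape13 <- rEnrichment(n, m13, s13)
  ape15 <- rEnrichment(n, m15, s15)
  truth <- data.frame(
    roi_id = info$roi_id, group = group, category = category,
    infection_status = status, host_link = info$host_link,
    true_ape13C = ape13, true_ape15N = ape15,
    true_kC = NA_real_, true_kN = NA_real_,
    true_rC = NA_real_, true_rN = NA_real_)
  list(rois = ROISet(mask = matrix(0L, 1, 1), info = info), truth = truth)
}
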