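#' Basal area from circumference at breast height
#'
#' BA = CBH^2 / (4 pi): the cross-sectional stem area of a circle with
#' circumference CBH.
#'
#' @param cbh Circumference at breast height (m), > 0.
#' @return Basal area (m2).
#' @examples
#' basal_area(2 * pi)  # pi
#' @export
basal_area <- function(cbh) {
  if (any(!is.finite(cbh)) || any(cbh <= 0)) stop("cbh must be positive")
  cbh^2 / (4 * pi)
}

#' Generate a ground-truth coefficient set
#'
#' Draws a complete, mutually consistent set of model coefficients from
#' documented plausible ranges, so simulated field data have a known truth
#' that the fitting stages can be tested against. Growth: beta uniform in
#' \[0.02, 0.12\], interactions alpha small relative to beta (uniform in
#' \[-0.004, 0.002\], conspecific entries biased negative), theta = b = 0.75.
#' Litterfall: positive b1, b2, b3, with the distance-decay terms (b2, b3)
#' carrying a substantial share of trap mass, reflecting the strong distance
#' limitation of litter dispersal.
#' Decomposition: identity effects beta_i in the 20-60% band, small positive
#' diversity effects alpha_i and richness effect b5, weak mass effect b4.
#' Allometry: per-species biomass = a_s * BA^c_s from basal area.
#'
#' @param pool Character vector of species labels.
#' @param seed Integer seed; identical seeds give identical truths.
#' @return Object of class `"ground_truth"`: list with `growth`
#'   ([growth_params()]), `litterfall` ([litterfall_params()]), `decomp_C`
#'   and `decomp_N` ([decomp_params()]), `allometry` (data frame), `noise`
#'   (trap_sd_frac, bag_sd_pct), `carbon_fraction`, `nitrogen_fraction`.
#' @export
generate_ground_truth <- function(pool = species_pool(8), seed = NULL) {
  r <- length(pool)
  with_seed(seed, {
    beta_g <- stats::setNames(stats::runif(r, 0.02, 0.12), pool)
    alpha <- matrix(stats::runif(r * r, -0.004, 0.002), r, r,
                    dimnames = list(pool, pool))
    diag(alpha) <- -abs(diag(alpha)) - 0.001   # conspecific competition
    growth <- growth_params(beta_g, alpha, theta = 0.75, b = 0.75)
    lf <- litterfall_params(
      b1 = stats::setNames(stats::runif(r, 0.02, 0.06), pool),
      b2 = stats::setNames(stats::runif(r, 2, 6), pool),
      b3 = stats::setNames(stats::runif(r, 0.05, 0.15), pool))
    dc <- decomp_params(
      beta = stats::setNames(stats::runif(r, 20, 60), pool),
      alpha = stats::setNames(stats::runif(r, 1, 4), pool),
      b4 = stats::runif(1, -0.05, 0.05), b5 = stats::runif(1, 0.5, 2),
      element = "C")
    dn <- decomp_params(
      beta = stats::setNames(stats::runif(r, 15, 50), pool),
      alpha = stats::setNames(stats::runif(r, 1, 4), pool),
      b4 = stats::runif(1, -0.05, 0.05), b5 = stats::runif(1, 0.5, 2),
      element = "N")
    allom <- data.frame(
      species = pool,
      a = stats::runif(r, 3000, 8000),   # biomass units per m2 basal area
      c = stats::runif(r, 0.9, 1.1),
      stringsAsFactors = FALSE)
    structure(list(growth = growth, litterfall = lf,
                   decomp_C = dc, decomp_N = dn, allometry = allom,
                   noise = list(trap_sd_frac = 0.10, bag_sd_pct = 3),
                   carbon_fraction = stats::setNames(rep(0.45, r), pool),
                   nitrogen_fraction = stats::setNames(rep(0.015, r), pool)),
              class = "ground_truth")
  })
}

#' Generate a synthetic field dataset
#'
#' Emulates the field campaign: `n_pairs` tree pairs, each with a 1 m2 litter
#' trap between the two pair trees and up to 12 surrounding trees on a
#' grid-like geometry (pair stems 1.28 m apart, neighbours on a 1 m planting
#' grid). Stem positions carry Gaussian scatter (SD 0.25 m: planting error
#' plus stem lean at breast height after nine growing seasons) and each
#' neighbour beyond the pair survives with probability 0.85, as in a real
#' plantation where stems lean and trees die, so each trap sees its own
#' distance pattern and n <= 12 trees. Tree biomass comes from the allometric
#' chain (CBH -> basal area -> biomass); noise-free trap masses follow the
#' litterfall model with the truth coefficients plus Gaussian noise; each
#' pair's litterbag mirrors the trap's species composition (2 g fill), with
#' element loss following the decomposition model (truth coefficients, the
#' trap's total mass as the L covariate) plus Gaussian noise, clamped to
#' \[0, 100\].
#'
#' @param truth A [generate_ground_truth()] object.
#' @param n_pairs Number of tree pairs (default 180).
#' @param seed Integer seed.
#' @param trap_sd_frac Trap-mass noise SD as a fraction of each record's
#'   noise-free mass (default from `truth$noise`).
#' @param bag_sd_pct Bag-loss noise SD in percentage points (default from
#'   `truth$noise`).
#' @return Object of class `"field_dataset"`: list with `litter` (trap_id,
#'   species, litter_mass_g), `trees` (trap_id, tree_idx, species, cbh_m,
#'   biomass, distance_m), `bags` (bag_id, element, species, proportion,
#'   total_mass_g, fill_mass_g, richness, loss_pct), `pairs` (per-pair
#'   metadata) and `truth`.
#' @export
generate_field_dataset <- function(truth, n_pairs = 180L, seed = NULL,
                                   trap_sd_frac = truth$noise$trap_sd_frac,
                                   bag_sd_pct = truth$noise$bag_sd_pct) {
  stopifnot(n_pairs >= 1)
  pool <- names(truth$litterfall$b1)
  # trap at the origin; pair stems at +/-0.64 m; ten further neighbours on
  # the 1 m planting grid around the pair
  nb_xy <- rbind(
    matrix(c(-0.64, 0, 0.64, 0), 2, 2, byrow = TRUE),
    as.matrix(expand.grid(x = c(-1.64, -0.64, 0.64, 1.64), y = c(-1, 1))),
    matrix(c(-1.64, 0, 1.64, 0), 2, 2, byrow = TRUE))
  jitter_sd <- 0.25    # stem scatter: planting error + lean at breast height (m)
  survival <- 0.85     # neighbour survival beyond the pair itself
  with_seed(seed, {
    litter <- list(); trees <- list(); bags <- list(); pairs <- list()
    richness_levels <- c(1, 2, 4, 8)
    for (p in seq_len(n_pairs)) {
      r_plot <- sample(richness_levels[richness_levels <= length(pool)], 1)
      plot_sp <- sample(pool, r_plot)
      alive <- c(TRUE, TRUE, stats::runif(10) < survival)
      xy <- nb_xy[alive, , drop = FALSE] +
        matrix(stats::rnorm(2 * sum(alive), 0, jitter_sd), ncol = 2)
      dists <- pmax(sqrt(rowSums(xy^2)), 0.3)
      n_tree <- nrow(xy)
      sp <- sample(plot_sp, n_tree, replace = TRUE)
      sp[1:2] <- sample(plot_sp, 2, replace = (r_plot == 1))  # the pair itself
      cbh <- stats::runif(n_tree, 0.10, 0.60)
      ba <- basal_area(cbh)
      al <- truth$allometry[match(sp, truth$allometry$species), ]
      biomass <- al$a * ba^al$c
      trap_id <- sprintf("trap%03d", p)
      trees[[p]] <- data.frame(trap_id = trap_id, tree_idx = seq_len(n_tree),
                               species = sp, cbh_m = cbh, biomass = biomass,
                               distance_m = dists, stringsAsFactors = FALSE)
      mu <- vapply(unique(sp), function(s) {
        i <- sp == s
        truth$litterfall$b1[s] * sum(biomass[i]) +
          truth$litterfall$b2[s] * sum(1 / dists[i]) +
          truth$litterfall$b3[s] * sum(biomass[i] / dists[i])
      }, numeric(1))
      # proportional residual: SD is 10% of each record's noise-free mass,
      # so a 2 g catch is not swamped by the error of a 100 g one
      obs <- pmax(mu * (1 + stats::rnorm(length(mu), 0, trap_sd_frac)), 0)
      litter[[p]] <- data.frame(trap_id = trap_id, species = names(mu),
                                litter_mass_g = unname(obs),
                                stringsAsFactors = FALSE)
      # litterbag mirrors the trap composition; L covariate = trap total mass
      tot <- sum(obs)
      if (tot <= 0) next
      prop <- obs / tot
      S <- sum(prop > 0)
      bag_rows <- lapply(c("C", "N"), function(el) {
        par <- if (el == "C") truth$decomp_C else truth$decomp_N
        P <- stats::setNames(rep(0, length(pool)), pool)
        P[names(prop)] <- prop
        D_mu <- predict_decomposition(P, total_mass = tot, richness = S,
                                      params = par)
        D <- min(max(D_mu + stats::rnorm(1, 0, bag_sd_pct), 0), 100)
        data.frame(bag_id = sprintf("bag%03d", p), element = el,
                   species = names(prop), proportion = unname(prop),
                   total_mass_g = tot, fill_mass_g = 2,
                   richness = S, loss_pct = D, stringsAsFactors = FALSE)
      })
      bags[[p]] <- do.call(rbind, bag_rows)
      pairs[[p]] <- data.frame(trap_id = trap_id, plot_richness = r_plot,
                               stringsAsFactors = FALSE)
    }
    structure(list(litter = do.call(rbind, litter),
                   trees = do.call(rbind, trees),
                   bags = do.call(rbind, bags),
                   pairs = do.call(rbind, pairs),
                   truth = truth),
              class = "field_dataset")
  })
}
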