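#' Stand-level summary of one simulated forest
#'
#' Collapses the per-tree biomass field and the per-pixel litter and
#' decomposition maps of one stand into the stand-level response variables:
#' mean tree biomass per m2 (final year), mean and between-pixel SD of total
#' litterfall, mean pixel litter species richness, mean and between-pixel SD
#' of the loss rate per element, and total element loss per m2 (loss rate
#' times pixel litter element density, averaged over pixels). Masked
#' (zero-litter) pixels are excluded from decomposition summaries.
#'
#' @param biomass A [simulate_growth()] field.
#' @param litter A [litterfall_map()] from the same layout.
#' @param decomp Named list of [decomposition_map()] objects (e.g.
#'   `list(C = ..., N = ...)`).
#' @param layout The layout all maps were computed on.
#' @param H Optional precomputed heterogeneity score (scalar); computed from
#'   the layout (rook adjacency) if missing.
#' @param element_fraction Named list per element of per-species element mass
#'   fractions of litter (defaults: C = 0.45, N = 0.015 for every species).
#' @return One-row data frame (a `StandSummary`).
#' @export
summarize_stand <- function(biomass, litter, decomp, layout, H = NULL,
                            element_fraction = NULL) {
  if (!identical(dim(biomass)[1:2], dim(layout$grid)))
    stop("biomass field and layout grids have mismatched shapes")
  if (!identical(dim(litter$total), dim(decomp[[1]]$D)))
    stop("litter and decomposition maps have mismatched shapes")
  if (is.null(H)) H <- heterogeneity(layout)$H
  fin <- final_biomass(biomass)
  out <- data.frame(
    mixture = paste(layout$mixture, collapse = "+"),
    richness = length(layout$mixture),
    design = layout$design,
    H = H,
    mean_biomass = sum(fin) / layout$plot_area,
    mean_litterfall = mean(litter$total),
    sd_litterfall = stats::sd(as.vector(litter$total)),
    mean_pixel_richness = mean(litter$richness),
    stringsAsFactors = FALSE)
  sp <- dimnames(litter$species)[[3]]
  for (el in names(decomp)) {
    D <- decomp[[el]]$D
    ok <- !is.na(D)
    frac <- .element_fraction(element_fraction, el, sp)
    # pixel element density (g/m2) = sum_s species mass * element fraction
    dens <- matrix(0, nrow(D), ncol(D))
    for (s in sp) dens <- dens + litter$species[, , s] * frac[s]
    loss <- D[ok] / 100 * dens[ok]
    out[[paste0("mean_D_", el)]] <- mean(D[ok])
    out[[paste0("sd_D_", el)]] <- stats::sd(D[ok])
    out[[paste0("total_loss_", el)]] <-
      sum(loss) / length(D) * 1        # mean over all pixels, g/m2
  }
  out
}

.element_fraction <- function(element_fraction, el, sp) {
  if (!is.null(element_fraction) && !is.null(element_fraction[[el]])) {
    f <- element_fraction[[el]]
    if (is.null(names(f))) f <- stats::setNames(rep(f[1], length(sp)), sp)
    return(f[sp])
  }
  stats::setNames(rep(if (el == "C") 0.45 else 0.015, length(sp)), sp)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the species pool, the
#' mixtures per richness level, the design list, simulation length and the
#' coefficient sets. The study-scale configuration is richness 2 with all 56
#' permutations and richness 4 and 8 with 1000 sampled permutations each,
#' planted across the 8 gradient levels plus mini-block, double-line and
#' single-line designs.
#'
#' @param pool Species pool.
#' @param richness Integer vector of richness levels.
#' @param n_perm Per-level permutation counts, `"all"` or integers (recycled).
#' @param designs Character vector; `"gradient"` expands to the 8-level
#'   block-to-random gradient, other entries are [make_layout()] designs.
#' @param gradient_levels Number of gradient levels (default 8).
#' @param gradient_chains,gradient_swaps Search effort for
#'   [make_heterogeneity_gradient()] (defaults 50 chains of 2000 swaps).
#' @param years Growth years (default 10).
#' @param seed Master seed; per-stand seeds are derived from it.
#' @param params List with `growth`, `litterfall` and `decomp` (named list
#'   per element) coefficient objects, e.g. from [generate_ground_truth()].
#' @param element_fraction Passed to [summarize_stand()].
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(pool = species_pool(8),
                              richness = c(2, 4, 8),
                              n_perm = list("all", 1000L, 1000L),
                              designs = c("gradient", "miniblock",
                                          "double_line", "single_line"),
                              gradient_levels = 8L,
                              gradient_chains = 50L, gradient_swaps = 2000L,
                              years = 10L, seed = 1L, params,
                              element_fraction = NULL) {
  if (!is.list(n_perm)) n_perm <- as.list(n_perm)
  n_perm <- rep_len(n_perm, length(richness))
  structure(list(pool = pool, richness = richness, n_perm = n_perm,
                 designs = designs, gradient_levels = gradient_levels,
                 gradient_chains = gradient_chains,
                 gradient_swaps = gradient_swaps,
                 years = years, seed = seed, params = params,
                 element_fraction = element_fraction),
            class = "experiment_config")
}

#' Run the factorial planting-design experiment
#'
#' For every mixture permutation at every richness level, builds each
#' requested design's layout(s), simulates growth, predicts the litterfall
#' and decomposition maps, and returns one [summarize_stand()] row per
#' (mixture x design). Deterministic given the config seed. Stage failures
#' are caught, recorded in the `error` column, and do not stop the run.
#'
#' @param config An [experiment_config()].
#' @param progress Print a line per mixture (default FALSE).
#' @return Data frame of stand summaries with seed and provenance columns.
#' @export
run_experiment <- function(config, progress = FALSE) {
  rows <- list()
  par <- config$params
  for (li in seq_along(config$richness)) {
    r <- config$richness[[li]]
    mixes <- mixture_permutations(config$pool, r, config$n_perm[[li]],
                                  seed = config$seed + li)
    for (mi in seq_along(mixes)) {
      mix <- mixes[[mi]]
      stand_seed <- (config$seed * 10007L + li * 1009L + mi) %% .Machine$integer.max
      layouts <- list()
      for (d in config$designs) {
        if (d == "gradient") {
          layouts <- c(layouts, make_heterogeneity_gradient(
            mix, levels = config$gradient_levels, seed = stand_seed,
            n_chains = config$gradient_chains,
            max_swaps = config$gradient_swaps))
        } else {
          layouts <- c(layouts, list(make_layout(mix, d, seed = stand_seed)))
        }
      }
      if (progress)
        message(sprintf("richness %d, mixture %d/%d (%s): %d layouts",
                        r, mi, length(mixes), paste(mix, collapse = "+"),
                        length(layouts)))
      for (lay in layouts) {
        res <- tryCatch({
          field <- simulate_growth(lay, par$growth, years = config$years)
          lmap <- litterfall_map(lay, final_biomass(field), par$litterfall)
          dmaps <- lapply(par$decomp, function(p) decomposition_map(lmap, p))
          s <- summarize_stand(field, lmap, dmaps, lay,
                               H = if (is.null(lay$H)) NULL else lay$H,
                               element_fraction = config$element_fraction)
          s$seed <- stand_seed
          s$error <- NA_character_
          s
        }, error = function(e) {
          data.frame(mixture = paste(mix, collapse = "+"), richness = r,
                     design = lay$design, H = NA_real_, mean_biomass = NA_real_,
                     mean_litterfall = NA_real_, sd_litterfall = NA_real_,
                     mean_pixel_richness = NA_real_, seed = stand_seed,
                     error = conditionMessage(e), stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  all_names <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(x) {
    x[setdiff(all_names, names(x))] <- NA
    x[all_names]
  })
  do.call(rbind, rows)
}

#' Richness x heterogeneity interaction model
#'
#' Fits the reporting model `response ~ richness * H` (heterogeneity
#' continuous by default, or as the ordinal design factor) on a table of
#' stand summaries, and returns coefficients plus the interaction ANOVA.
#'
#' @param summaries Data frame from [run_experiment()].
#' @param response Name of the response column.
#' @param heterogeneity `"H"` (continuous) or `"design"` (ordinal factor).
#' @return List with `model` (the `lm`), `coefficients`, `interaction_F`,
#'   `interaction_p`, `r_squared`.
#' @export
interaction_analysis <- function(summaries, response,
                                 heterogeneity = c("H", "design")) {
  heterogeneity <- match.arg(heterogeneity)
  d <- summaries[!is.na(summaries[[response]]), , drop = FALSE]
  if (length(unique(d$richness)) < 2)
    stop("summaries must span at least 2 richness levels")
  if (heterogeneity == "H") {
    if (length(unique(d$H)) < 2) stop("summaries must span >= 2 heterogeneity levels")
    if (stats::var(d[[response]]) == 0) stop("degenerate response variance")
    fml <- stats::reformulate("richness * H", response)
  } else {
    d$design <- factor(d$design)
    if (nlevels(d$design) < 2) stop("summaries must span >= 2 designs")
    fml <- stats::reformulate("richness * design", response)
  }
  fit <- stats::lm(fml, data = d)
  an <- stats::anova(fit)
  irow <- grep(":", rownames(an))
  list(model = fit,
       coefficients = stats::coef(fit),
       interaction_F = an[irow, "F value"][1],
       interaction_p = an[irow, "Pr(>F)"][1],
       r_squared = summary(fit)$r.squared)
}
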