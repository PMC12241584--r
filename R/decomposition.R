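#' Decomposition model parameters
#'
#' Coefficients of the additive diversity-interaction decomposition model:
#' loss rate D (% of initial element content) of a litter mixture with
#' species proportions P_i, total mass L and species richness S is
#' D = sum_i beta_i P_i + sum_(i<j) (alpha_i + alpha_j) P_i P_j + b4 L + b5 S,
#' clamped to \[0, 100\]. beta_i is the species identity effect (the
#' monoculture rate up to the L and S terms), alpha_i the species' additive
#' contribution to pairwise mixing effects.
#'
#' @param beta,alpha Named numeric vectors (same species names), % scale.
#' @param b4 Effect of total litter mass (% per mass unit).
#' @param b5 Effect of litter species richness (% per species).
#' @param element `"C"` or `"N"`; carbon and nitrogen are fitted and
#'   predicted as independent coefficient sets.
#' @param uncertainty Optional data frame attached as-is.
#' @return Object of class `"decomp_params"`.
#' @export
decomp_params <- function(beta, alpha, b4, b5, element = c("C", "N"),
                          uncertainty = NULL) {
  element <- match.arg(element)
  sp <- names(beta)
  if (is.null(sp) || !identical(names(alpha), sp))
    stop("beta and alpha must be named by the same species")
  stopifnot(is.finite(beta), is.finite(alpha), is.finite(b4), is.finite(b5))
  structure(list(beta = beta, alpha = alpha, b4 = b4, b5 = b5,
                 element = element, uncertainty = uncertainty),
            class = "decomp_params")
}

#' Predict the decomposition loss rate of one litter mixture
#'
#' @param proportions Named numeric vector of per-species litter-mass
#'   proportions, summing to 1 (tolerance 1e-6). Species absent from the
#'   mixture may be included with proportion 0.
#' @param total_mass Total litter mass L (>= 0), in the units the
#'   coefficients were fitted in.
#' @param richness Litter species richness S (defaults to the number of
#'   strictly positive proportions).
#' @param params A [decomp_params()] object covering all species with
#'   positive proportion.
#' @return Loss rate D in %, clamped to \[0, 100\].
#' @export
predict_decomposition <- function(proportions, total_mass,
                                  richness = sum(proportions > 0), params) {
  if (abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must sum to 1 (tolerance 1e-6)")
  stopifnot(total_mass >= 0)
  if (total_mass > 0 && richness < 1) stop("richness must be >= 1 when mass > 0")
  sp <- names(proportions)
  if (is.null(sp) || anyNA(match(sp[proportions > 0], names(params$beta))))
    stop("all species with positive proportion must appear in params")
  i <- match(sp, names(params$beta))
  beta <- params$beta[i]; alpha <- params$alpha[i]
  identity <- sum(beta * proportions, na.rm = TRUE)
  # explicit unordered-pair sum: sum_(i<j) (alpha_i + alpha_j) P_i P_j
  pair <- 0
  pos <- which(proportions > 0)
  if (length(pos) >= 2) {
    for (a in seq_along(pos)[-length(pos)]) {
      for (b in seq(a + 1L, length(pos))) {
        ia <- pos[a]; ib <- pos[b]
        pair <- pair + (alpha[ia] + alpha[ib]) * proportions[ia] * proportions[ib]
      }
    }
  }
  D <- identity + pair + params$b4 * total_mass + params$b5 * richness
  unname(min(max(D, 0), 100))
}

# vectorised linear predictor over a matrix of proportions (rows = mixtures),
# using the identity sum_(i<j)(a_i+a_j)P_iP_j = sum_i a_i P_i (1 - P_i)
# valid when rows sum to 1
.decomp_linpred <- function(P, L, S, params) {
  sp <- colnames(P)
  beta <- params$beta[sp]; alpha <- params$alpha[sp]
  as.vector(P %*% beta + (P * (1 - P)) %*% alpha + params$b4 * L + params$b5 * S)
}

#' Fit the decomposition model to litterbag records
#'
#' The model is linear in all coefficients given the observed proportions,
#' total mass and richness: the design has one column P_i per species
#' identity term, one column P_i (1 - P_i) per diversity term (the
#' unordered-pair sum collapses to this when proportions sum to 1), plus L
#' and S, with no intercept. `method = "ls"` is ordinary least squares;
#' `method = "bayes"` samples the model with JAGS (4 chains, 3000 iterations,
#' 1000 warm-up). Priors are normal(0, 50^2): weakly informative on the
#' percent scale, where identity effects can span most of the 0-100 range.
#'
#' @param bags Data frame with columns `bag_id`, `element`, `species`,
#'   `proportion`, `total_mass_g`, `richness`, `loss_pct` (long over species
#'   within bag), as produced by [generate_field_dataset()].
#' @param element `"C"` or `"N"`: which element's loss to fit.
#' @param method `"ls"` or `"bayes"`.
#' @param chains,iter,warmup Sampler settings (bayes only).
#' @param seed Integer seed (bayes only).
#' @return A [decomp_params()] object.
#' @export
fit_decomposition <- function(bags, element = c("C", "N"),
                              method = c("ls", "bayes"),
                              chains = 4L, iter = 3000L, warmup = 1000L,
                              seed = NULL) {
  element <- match.arg(element)
  method <- match.arg(method)
  b <- bags[bags$element == element, , drop = FALSE]
  if (nrow(b) == 0) stop("no bags for element ", element)
  species <- sort(unique(b$species))
  ids <- unique(b$bag_id)
  P <- matrix(0, length(ids), length(species),
              dimnames = list(ids, species))
  P[cbind(match(b$bag_id, ids), match(b$species, species))] <- b$proportion
  first <- b[!duplicated(b$bag_id), ]
  first <- first[match(ids, first$bag_id), ]
  L <- first$total_mass_g; S <- first$richness; y <- first$loss_pct
  if (length(unique(S)) < 2)
    stop("bags cover a single richness level; b5 (richness effect) is unidentifiable")
  Pdiv <- P * (1 - P)
  if (all(Pdiv == 0))
    stop(sprintf("all bags are monospecific; diversity terms unidentifiable: %s",
                 paste0("alpha_", species, collapse = ", ")))
  X <- cbind(P, Pdiv, L = L, S = S)
  colnames(X) <- c(paste0("beta_", species), paste0("alpha_", species), "b4", "b5")
  keep <- apply(X, 2, function(v) stats::var(v) > 0 | any(v != 0))
  if (qr(X)$rank < ncol(X))
    stop(sprintf("unidentifiable decomposition design; deficient columns among: %s",
                 paste(colnames(X)[!keep], collapse = ", ")))
  if (method == "ls") {
    co <- stats::lm.fit(X, y)$coefficients
    unc <- NULL
  } else {
    draws <- .jags_linear(X, y, chains, iter, warmup, seed, coef_sd = 50,
                          names_out = colnames(X))
    co <- stats::setNames(as.vector(draws$mean), colnames(X))
    unc <- data.frame(term = colnames(X), sd = draws$sd, rhat = draws$rhat)
    if (any(unc$rhat > 1.05, na.rm = TRUE))
      warning("decomposition sampler: split R-hat above 1.05 for some coefficients")
  }
  decomp_params(co[paste0("beta_", species)] |> stats::setNames(species),
                co[paste0("alpha_", species)] |> stats::setNames(species),
                b4 = unname(co["b4"]), b5 = unname(co["b5"]),
                element = element, uncertainty = unc)
}

#' Decomposition map over the stand
#'
#' Applies the decomposition model to every pixel of a [litterfall_map()]:
#' per-species masses become proportions, total pixel mass enters as L and
#' pixel litter richness as S. Pixels with zero litter have no defined loss
#' rate and are returned as `NA` (masked from stand summaries).
#'
#' @param litter A [litterfall_map()] result.
#' @param params A [decomp_params()] object.
#' @param mass_scale Multiplier converting pixel total mass density to the
#'   mass units the coefficients were fitted in (default 1).
#' @return Object of class `"decomposition_map"`: list with `D` (matrix, %,
#'   clamped to \[0, 100\], `NA` where masked) and `element`.
#' @export
decomposition_map <- function(litter, params, mass_scale = 1) {
  sp <- dimnames(litter$species)[[3]]
  npx <- nrow(litter$total)
  P <- matrix(litter$species, npx * npx, length(sp), dimnames = list(NULL, sp))
  tot <- as.vector(litter$total)
  ok <- tot > 0
  D <- rep(NA_real_, npx * npx)
  if (any(ok)) {
    Pn <- P[ok, , drop = FALSE] / tot[ok]
    lp <- .decomp_linpred(Pn, tot[ok] * mass_scale,
                          as.vector(litter$richness)[ok], params)
    D[ok] <- pmin(pmax(lp, 0), 100)
  }
  structure(list(D = matrix(D, npx, npx), element = params$element),
            class = "decomposition_map")
}
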