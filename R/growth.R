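#' Growth model parameters
#'
#' Parameters of the neighbourhood growth model: annual biomass increment of
#' tree i is beta_s(i) * B_i^theta plus the sum over its Moore neighbours j of
#' alpha_s(i),s(j) * B_j^b. beta scales species-specific intrinsic growth,
#' alpha the pairwise interaction (negative = competition), and theta and b
#' are allometric scaling exponents allowing sublinear growth.
#'
#' @param beta Named numeric vector of intrinsic growth coefficients, one per
#'   species.
#' @param alpha Square numeric matrix of interaction coefficients with
#'   dimnames matching `names(beta)`; `alpha[s, s2]` is the effect of a
#'   neighbour of species s2 on a focal tree of species s.
#' @param theta,b Allometric exponents (dimensionless).
#' @return Object of class `"growth_params"`.
#' @export
growth_params <- function(beta, alpha, theta = 0.75, b = 0.75) {
  sp <- names(beta)
  if (is.null(sp)) stop("beta must be named by species")
  if (!is.matrix(alpha) || nrow(alpha) != ncol(alpha))
    stop("alpha must be a square matrix")
  if (!identical(rownames(alpha), sp) || !identical(colnames(alpha), sp))
    stop("alpha dimnames must match names(beta)")
  stopifnot(is.finite(beta), is.finite(alpha), is.finite(theta), is.finite(b))
  structure(list(beta = beta, alpha = alpha, theta = theta, b = b),
            class = "growth_params")
}

#' One annual growth step
#'
#' Advances every tree's biomass by one year. Neighbour sums run over the
#' Moore neighbours present in the grid (edge trees sum fewer terms). Biomass
#' is floored at a small positive constant so strongly negative interactions
#' cannot drive it non-positive.
#'
#' @param biomass Numeric matrix of current biomasses, same shape as the
#'   layout grid, strictly positive.
#' @param layout A [make_layout()] object.
#' @param params A [growth_params()] object covering every species present.
#' @param nb Adjacency for the interaction sum (default Moore).
#' @param floor Lower clamp for biomass (default 1e-6).
#' @return Numeric matrix of next-year biomasses.
#' @export
growth_step <- function(biomass, layout, params, nb = neighborhood("moore"),
                        floor = 1e-6) {
  if (!all(is.finite(biomass))) stop("non-finite biomass input")
  if (any(biomass <= 0)) stop("biomass must be strictly positive")
  sp <- names(params$beta)
  sidx <- matrix(match(layout$grid, sp), nrow(biomass), ncol(biomass))
  if (anyNA(sidx)) stop("layout contains species missing from params")
  inter <- .interaction_sum(biomass^params$b, sidx, params$alpha, nb)
  out <- biomass + params$beta[sidx] * biomass^params$theta + inter
  pmax(matrix(out, nrow(biomass), ncol(biomass)), floor)
}

# sum over neighbours j of alpha[s(i), s(j)] * Bb[j], truncated at edges
.interaction_sum <- function(Bb, sidx, alpha, nb) {
  nr <- nrow(Bb); nc <- ncol(Bb)
  acc <- matrix(0, nr, nc)
  for (k in seq_len(nrow(nb$offsets))) {
    dr <- nb$offsets[k, 1]; dc <- nb$offsets[k, 2]
    rows <- seq_len(nr); cols <- seq_len(nc)
    rok <- rows + dr >= 1 & rows + dr <= nr
    cok <- cols + dc >= 1 & cols + dc <= nc
    if (!any(rok) || !any(cok)) next
    tr <- rows[rok]; tc <- cols[cok]
    a <- matrix(alpha[cbind(as.vector(sidx[tr, tc, drop = FALSE]),
                            as.vector(sidx[tr + dr, tc + dc, drop = FALSE]))],
                length(tr), length(tc))
    acc[tr, tc] <- acc[tr, tc] + a * Bb[tr + dr, tc + dc, drop = FALSE]
  }
  acc
}

#' Simulate tree growth on a layout
#'
#' Iterates [growth_step()] from a uniform starting biomass and records the
#' full trajectory. Deterministic given its inputs.
#'
#' @param layout A [make_layout()] object.
#' @param params A [growth_params()] object.
#' @param years Number of annual steps (default 10).
#' @param b0 Starting biomass for every tree (model units; default 100).
#' @param nb Adjacency (default Moore).
#' @param overflow Guard: any biomass above this aborts with the offending
#'   step named (default 1e12).
#' @return Object of class `"biomass_field"`: numeric array
#'   `nrow x ncol x (years + 1)`, slice 1 the starting field.
#' @export
simulate_growth <- function(layout, params, years = 10L, b0 = 100,
                            nb = neighborhood("moore"), overflow = 1e12) {
  stopifnot(years >= 1)
  nr <- nrow(layout$grid); nc <- ncol(layout$grid)
  traj <- array(NA_real_, c(nr, nc, years + 1L))
  B <- matrix(b0, nr, nc)
  traj[, , 1] <- B
  for (t in seq_len(years)) {
    B <- growth_step(B, layout, params, nb)
    if (any(B > overflow))
      stop(sprintf("biomass diverged above %g at step %d", overflow, t))
    traj[, , t + 1L] <- B
  }
  structure(traj, class = c("biomass_field", "array"))
}

#' Final-year biomass matrix of a trajectory
#' @param field A [simulate_growth()] result.
#' @return Numeric matrix (last slice).
#' @export
final_biomass <- function(field) {
  field[, , dim(field)[3]]
}
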