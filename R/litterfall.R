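#' Litterfall model parameters
#'
#' Species-specific coefficients of the distance-decay litterfall model: the
#' litter mass of species i collected at a point is
#' b1_i * sum(B_ij) + b2_i * sum(1/d_ij) + b3_i * sum(B_ij / d_ij), summing
#' over the surrounding trees j of species i, with biomass B_ij and distance
#' d_ij (m) from the point.
#'
#' @param b1,b2,b3 Named numeric vectors (same species names): mass per
#'   biomass, mass x m, and mass x m per biomass respectively.
#' @param uncertainty Optional data frame of per-coefficient uncertainty
#'   (attached as-is, e.g. posterior SDs from [fit_litterfall()]).
#' @return Object of class `"litterfall_params"`.
#' @export
litterfall_params <- function(b1, b2, b3, uncertainty = NULL) {
  sp <- names(b1)
  if (is.null(sp)) stop("coefficients must be named by species")
  if (!identical(names(b2), sp) || !identical(names(b3), sp))
    stop("b1, b2, b3 must share species names")
  stopifnot(is.finite(b1), is.finite(b2), is.finite(b3))
  structure(list(b1 = b1, b2 = b2, b3 = b3, uncertainty = uncertainty),
            class = "litterfall_params")
}

#' Per-species litterfall prediction at one point
#'
#' Reference single-pixel implementation: the `k` trees nearest to the point
#' contribute, grouped by species; negative model output is clamped to 0.
#' Distances are centre-to-stem in metres, floored at `d_min` so points on a
#' stem do not blow up the 1/d terms.
#'
#' @param pixel_center Numeric length-2 `(x, y)` in metres.
#' @param layout A [make_layout()] object.
#' @param biomass Numeric matrix of per-tree biomass (layout shape).
#' @param params A [litterfall_params()] object.
#' @param k Number of nearest contributing trees (default 12, mirroring the
#'   12 trees surrounding a litter trap in the field calibration).
#' @param d_min Distance floor in metres (default 0.05, half a pixel).
#' @return Named numeric vector of litter mass density (g/m2) per layout
#'   species.
#' @export
predict_pixel_litterfall <- function(pixel_center, layout, biomass, params,
                                     k = 12L, d_min = 0.05) {
  if (k < 1) stop("k must be >= 1")
  pos <- tree_positions(layout)
  d <- sqrt((pos$x - pixel_center[1])^2 + (pos$y - pixel_center[2])^2)
  near <- order(d)[seq_len(min(k, nrow(pos)))]
  d <- pmax(d[near], d_min)
  B <- as.vector(biomass)[near]
  sp_near <- pos$species[near]
  out <- numeric(length(layout$mixture))
  names(out) <- layout$mixture
  for (s in unique(sp_near)) {
    i <- sp_near == s
    out[s] <- params$b1[s] * sum(B[i]) + params$b2[s] * sum(1 / d[i]) +
      params$b3[s] * sum(B[i] / d[i])
  }
  pmax(out, 0)
}

# pixel-to-tree nearest-neighbour geometry. Depends only on the grid shape,
# spacing, pixel size and k, so it is computed once and cached.
.geom_cache <- new.env(parent = emptyenv())

stand_pixel_geometry <- function(n_grid = 16L, spacing = 1, pixel = 0.1,
                                 k = 12L, d_min = 0.05) {
  key <- paste(n_grid, spacing, pixel, k, d_min, sep = "|")
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  extent <- (n_grid - 1) * spacing
  n_pix <- as.integer(round(extent / pixel))
  centers <- pixel / 2 + pixel * (seq_len(n_pix) - 1L)
  # trees in column-major order to match as.vector(grid)
  tx <- rep((seq_len(n_grid) - 1) * spacing, each = n_grid)
  ty <- rep((seq_len(n_grid) - 1) * spacing, times = n_grid)
  px <- rep(centers, each = n_pix)   # pixel index = (ix - 1) * n_pix + iy
  py <- rep(centers, times = n_pix)
  n_tree <- n_grid * n_grid
  npx <- n_pix * n_pix
  idx <- matrix(0L, npx, k)
  dst <- matrix(0, npx, k)
  d2 <- matrix(0, npx, n_tree)
  for (j in seq_len(n_tree)) d2[, j] <- (px - tx[j])^2 + (py - ty[j])^2
  for (p in seq_len(npx)) {
    o <- order(d2[p, ])[seq_len(k)]
    idx[p, ] <- o
    dst[p, ] <- sqrt(d2[p, o])
  }
  g <- list(n_pix = n_pix, centers = centers, idx = idx,
            dist = pmax(dst, d_min), k = k)
  .geom_cache[[key]] <- g
  g
}

#' Litterfall map over the whole stand
#'
#' Evaluates the litterfall model at every 0.1 x 0.1 m pixel centre of the
#' stand (150 x 150 pixels for the default 16 x 16 grid at 1 m spacing).
#' Per pixel it records the clamped per-species litter mass density, the
#' total, and the litter species richness (number of species with strictly
#' positive mass).
#'
#' @inheritParams predict_pixel_litterfall
#' @param pixel Pixel side length in metres (default 0.1).
#' @param biomass_scale Multiplier applied to `biomass` before entering the
#'   model, linking growth-model units to the biomass units the litterfall
#'   coefficients were fitted in (default 1).
#' @return Object of class `"litter_map"`: list with `species` (array
#'   n_pix x n_pix x r, dimnames on species), `total` (matrix), `richness`
#'   (integer matrix), `pixel` (m), `pixel_area` (m2).
#' @export
litterfall_map <- function(layout, biomass, params, k = 12L, d_min = 0.05,
                           pixel = 0.1, biomass_scale = 1) {
  g <- stand_pixel_geometry(nrow(layout$grid), layout$spacing, pixel, k, d_min)
  sp_tree <- as.vector(layout$grid)
  B_tree <- as.vector(biomass) * biomass_scale
  sp_near <- matrix(sp_tree[g$idx], nrow(g$idx), ncol(g$idx))
  B_near <- matrix(B_tree[g$idx], nrow(g$idx), ncol(g$idx))
  inv_d <- 1 / g$dist
  r <- length(layout$mixture)
  npx <- g$n_pix
  arr <- array(0, c(npx, npx, r), dimnames = list(NULL, NULL, layout$mixture))
  for (s in layout$mixture) {
    m <- sp_near == s
    val <- params$b1[s] * rowSums(B_near * m) +
      params$b2[s] * rowSums(inv_d * m) +
      params$b3[s] * rowSums(B_near * inv_d * m)
    val[rowSums(m) == 0] <- 0          # species absent among contributors
    arr[, , s] <- matrix(pmax(val, 0), npx, npx)
  }
  total <- apply(arr, c(1, 2), sum)
  richness <- apply(arr > 0, c(1, 2), sum)
  structure(list(species = arr, total = total, richness = richness,
                 pixel = pixel, pixel_area = pixel^2),
            class = "litter_map")
}

#' Fit the litterfall model to trap records
#'
#' The model is linear in (b1_i, b2_i, b3_i) given the trap geometry, so each
#' species is fitted independently on the traps where it has at least one
#' surrounding tree, with predictors S1 = sum(B_ij), S2 = sum(1/d_ij),
#' S3 = sum(B_ij/d_ij) and no intercept. `method = "ls"` uses ordinary least
#' squares (the posterior mean under a flat prior); `method = "bayes"` samples
#' the same model with Gaussian noise and weakly informative normal(0, 10^2)
#' priors via JAGS (4 chains, 3000 iterations, 1000 warm-up) and returns
#' posterior means with convergence diagnostics.
#'
#' @param traps A list with elements `litter` (data frame: trap_id, species,
#'   litter_mass_g) and `trees` (data frame: trap_id, species, biomass,
#'   distance_m), as produced by [generate_field_dataset()].
#' @param method `"ls"` or `"bayes"`.
#' @param chains,iter,warmup Sampler settings (bayes only).
#' @param seed Integer seed (bayes only).
#' @return A [litterfall_params()] object; for `"bayes"` the `uncertainty`
#'   slot holds posterior SDs and split-chain R-hat per coefficient.
#' @export
fit_litterfall <- function(traps, method = c("ls", "bayes"),
                           chains = 4L, iter = 3000L, warmup = 1000L,
                           seed = NULL) {
  method <- match.arg(method)
  des <- litterfall_design(traps)
  species <- sort(unique(des$species))
  est <- matrix(NA_real_, length(species), 3,
                dimnames = list(species, c("b1", "b2", "b3")))
  unc <- NULL
  for (s in species) {
    d <- des[des$species == s, , drop = FALSE]
    X <- as.matrix(d[, c("S1", "S2", "S3")])
    if (qr(X)$rank < 3L) {
      vv <- apply(X, 2, stats::var)
      stop(sprintf("rank-deficient litterfall design for %s; collinear terms: %s",
                   s, paste(c("S1", "S2", "S3")[vv < 1e-12 | is.na(vv)],
                            collapse = ", ")))
    }
    if (method == "ls") {
      fit <- stats::lm.fit(X, d$litter_mass_g)
      est[s, ] <- fit$coefficients
    } else {
      draws <- .jags_linear(X, d$litter_mass_g, chains, iter, warmup, seed)
      est[s, ] <- colMeans(draws$mean)
      unc <- rbind(unc, data.frame(species = s, term = c("b1", "b2", "b3"),
                                   sd = draws$sd, rhat = draws$rhat))
    }
  }
  if (!is.null(unc) && any(unc$rhat > 1.05, na.rm = TRUE))
    warning("litterfall sampler: split R-hat above 1.05 for some coefficients")
  litterfall_params(stats::setNames(est[, 1], species),
                    stats::setNames(est[, 2], species),
                    stats::setNames(est[, 3], species),
                    uncertainty = unc)
}

# one row per (trap, species with >= 1 surrounding tree): Eq. 2 predictor sums
# and the observed per-species trap mass (0 when the species shed nothing)
litterfall_design <- function(traps) {
  tr <- traps$trees
  agg <- stats::aggregate(
    cbind(S1 = tr$biomass, S2 = 1 / tr$distance_m,
          S3 = tr$biomass / tr$distance_m),
    by = list(trap_id = tr$trap_id, species = tr$species), FUN = sum)
  li <- traps$litter
  key <- paste(agg$trap_id, agg$species)
  obs <- li$litter_mass_g[match(key, paste(li$trap_id, li$species))]
  agg$litter_mass_g <- ifelse(is.na(obs), 0, obs)
  agg
}

# Gaussian linear model with normal(0, 100) coefficient priors in JAGS;
# returns posterior means/SDs and split-chain R-hat
.jags_linear <- function(X, y, chains, iter, warmup, seed,
                         coef_sd = 10, names_out = colnames(X)) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("method = 'bayes' requires the rjags package")
  p <- ncol(X)
  model <- sprintf("
    model {
      for (i in 1:N) {
        mu[i] <- inprod(X[i, ], beta[])
        y[i] ~ dnorm(mu[i], tau)
      }
      for (j in 1:P) { beta[j] ~ dnorm(0, %.8f) }
      sigma ~ dnorm(0, 1e-4) T(0, )
      tau <- pow(sigma, -2)
    }", 1 / coef_sd^2)
  inits <- lapply(seq_len(chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = if (is.null(seed)) i else seed * 1000L + i)
  })
  jm <- rjags::jags.model(textConnection(model),
                          data = list(X = X, y = y, N = nrow(X), P = p),
                          inits = inits, n.chains = chains, quiet = TRUE)
  update(jm, warmup, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", n.iter = iter - warmup,
                              progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))
  rhat <- vapply(seq_len(p), function(j) {
    .split_rhat(lapply(samp, function(ch) as.matrix(ch)[, j]))
  }, numeric(1))
  list(mean = matrix(colMeans(mat), 1, p, dimnames = list(NULL, names_out)),
       sd = apply(mat, 2, stats::sd), rhat = rhat, draws = mat)
}

# split-chain potential scale reduction factor
.split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
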