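demo_decomp <- function() {
  decomp_params(beta = c(a = 30, b = 50), alpha = c(a = 2, b = 4),
                b4 = 0.5, b5 = 1.5, element = "C")
}

test_that("the diversity-interaction predictor matches hand substitution", {
  par <- demo_decomp()
  # monospecific bag: pair term vanishes
  expect_equal(predict_decomposition(c(a = 1, b = 0), total_mass = 2,
                                     richness = 1, params = par),
               30 + 0.5 * 2 + 1.5 * 1)
  # two species at P = 0.5: (b1+b2)/2 + (a1+a2)/4 + b4 L + 2 b5
  expect_equal(predict_decomposition(c(a = 0.5, b = 0.5), total_mass = 2,
                                     richness = 2, params = par),
               (30 + 50) / 2 + (2 + 4) / 4 + 0.5 * 2 + 1.5 * 2)
  # clamping at 100
  hot <- decomp_params(beta = c(a = 95, b = 95), alpha = c(a = 40, b = 40),
                       b4 = 1, b5 = 5, element = "C")
  expect_equal(predict_decomposition(c(a = 0.5, b = 0.5), 2, 2, hot), 100)
  # proportions must sum to 1
  expect_error(predict_decomposition(c(a = 0.6, b = 0.6), 2, 2, par), "sum")
})

test_that("prediction is invariant under joint species relabeling", {
  par <- demo_decomp()
  flipped <- decomp_params(beta = c(b = 50, a = 30), alpha = c(b = 4, a = 2),
                           b4 = 0.5, b5 = 1.5, element = "C")
  P <- c(a = 0.3, b = 0.7)
  expect_equal(predict_decomposition(P, 2, 2, par),
               predict_decomposition(P[c("b", "a")], 2, 2, flipped))
})

test_that("without diversity, mass and richness terms the model is additive", {
  par <- decomp_params(beta = c(a = 30, b = 50, c = 40),
                       alpha = c(a = 0, b = 0, c = 0),
                       b4 = 0, b5 = 0, element = "C")
  P <- c(a = 0.2, b = 0.5, c = 0.3)
  monos <- c(30, 50, 40)
  expect_equal(predict_decomposition(P, 2, 3, par), sum(P * monos))
})

test_that("least squares recovers decomposition coefficients from clean bags", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 31)
  ds <- generate_field_dataset(truth, n_pairs = 120, seed = 33,
                               trap_sd_frac = 0, bag_sd_pct = 0)
  for (el in c("C", "N")) {
    tru <- if (el == "C") truth$decomp_C else truth$decomp_N
    fit <- fit_decomposition(ds$bags, el, method = "ls")
    expect_equal(fit$beta, tru$beta, tolerance = 1e-6)
    expect_equal(fit$alpha, tru$alpha, tolerance = 1e-6)
    expect_equal(fit$b4, tru$b4, tolerance = 1e-6)
    expect_equal(fit$b5, tru$b5, tolerance = 1e-6)
  }
})

test_that("unidentifiable bag designs are rejected with the terms named", {
  mono_bags <- data.frame(
    bag_id = rep(paste0("m", 1:10), each = 1), element = "C",
    species = rep(c("a", "b"), 5), proportion = 1,
    total_mass_g = seq(10, 19), richness = 1,
    loss_pct = seq(30, 39))
  expect_error(fit_decomposition(mono_bags, "C"), "richness")
  mono_bags$richness <- rep(c(1, 2), 5)   # inconsistent but exercises alpha check
  expect_error(fit_decomposition(mono_bags, "C"), "alpha")
})

test_that("decomposition maps follow the litter map pixel by pixel", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 42)
  lay <- make_layout(pool, "random", seed = 12)
  B <- final_biomass(simulate_growth(lay, truth$growth))
  lmap <- litterfall_map(lay, B, truth$litterfall)
  dmap <- decomposition_map(lmap, truth$decomp_C)
  for (i in 60:69) for (j in 20:24) {
    P <- lmap$species[i, j, ] / lmap$total[i, j]
    ref <- predict_decomposition(P, lmap$total[i, j], lmap$richness[i, j],
                                 truth$decomp_C)
    expect_equal(dmap$D[i, j], ref, tolerance = 1e-10)
  }
  expect_true(all(dmap$D >= 0 & dmap$D <= 100, na.rm = TRUE))
})

test_that("uniform litter gives spatially constant decomposition", {
  sp <- c("a", "b")
  arr <- array(1, c(5, 5, 2), dimnames = list(NULL, NULL, sp))
  lmap <- structure(list(species = arr, total = apply(arr, c(1, 2), sum),
                         richness = matrix(2L, 5, 5), pixel = 0.1,
                         pixel_area = 0.01), class = "litter_map")
  dmap <- decomposition_map(lmap, demo_decomp())
  expect_equal(sd(as.vector(dmap$D)), 0)
  # monoculture map: D varies only through total mass L
  arr1 <- array(0, c(5, 5, 2), dimnames = list(NULL, NULL, sp))
  arr1[, , 1] <- matrix(seq(1, 25), 5, 5)
  lmap1 <- structure(list(species = arr1, total = apply(arr1, c(1, 2), sum),
                          richness = matrix(1L, 5, 5), pixel = 0.1,
                          pixel_area = 0.01), class = "litter_map")
  d1 <- decomposition_map(lmap1, demo_decomp())
  par <- demo_decomp()
  expect_equal(d1$D, 30 + par$b4 * lmap1$total + par$b5 * 1,
               ignore_attr = TRUE)
})

test_that("zero-litter pixels are masked, not treated as zero loss", {
  sp <- c("a", "b")
  arr <- array(0, c(2, 2, 2), dimnames = list(NULL, NULL, sp))
  arr[1, 1, 1] <- 5
  lmap <- structure(list(species = arr, total = apply(arr, c(1, 2), sum),
                         richness = (apply(arr > 0, c(1, 2), sum)),
                         pixel = 0.1, pixel_area = 0.01), class = "litter_map")
  dmap <- decomposition_map(lmap, demo_decomp())
  expect_false(is.na(dmap$D[1, 1]))
  expect_true(all(is.na(dmap$D[-1])))
})
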