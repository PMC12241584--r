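test_that("point predictions follow the distance-decay model exactly", {
  # one tree, d = 1 m, B = 100, (b1, b2, b3) = (0.1, 2, 0.05) -> 17 g/m2
  lay <- grid_layout(matrix("sp1", 1, 1))
  par <- litterfall_params(b1 = c(sp1 = 0.1), b2 = c(sp1 = 2),
                           b3 = c(sp1 = 0.05))
  L <- predict_pixel_litterfall(c(1, 0), lay, matrix(100, 1, 1), par, k = 1)
  expect_equal(unname(L["sp1"]), 0.1 * 100 + 2 * 1 + 0.05 * 100 * 1)

  # two identical equidistant trees double the single-tree prediction
  lay2 <- grid_layout(matrix("sp1", 1, 2))   # stems at x = 0 and x = 1
  L2 <- predict_pixel_litterfall(c(0.5, 1), lay2, matrix(100, 1, 2), par, k = 2)
  L1 <- predict_pixel_litterfall(c(0.5, 1), lay2, matrix(100, 1, 2), par, k = 1)
  expect_equal(unname(L2["sp1"]), 2 * unname(L1["sp1"]))

  expect_error(predict_pixel_litterfall(c(0, 0), lay, matrix(100, 1, 1), par,
                                        k = 0), "k")
})

test_that("with b2 = b3 = 0 only nearest-tree biomass matters", {
  pool <- species_pool(4)
  lay <- make_layout(pool, "random", seed = 2)
  B <- matrix(runif(256, 50, 200), 16, 16)
  par <- litterfall_params(
    b1 = setNames(1:4 / 10, pool),
    b2 = setNames(rep(0, 4), pool),
    b3 = setNames(rep(0, 4), pool))
  px <- c(7.3, 8.1)
  pred <- predict_pixel_litterfall(px, lay, B, par, k = 12)
  pos <- standlitter:::tree_positions(lay)
  d <- sqrt((pos$x - px[1])^2 + (pos$y - px[2])^2)
  near <- order(d)[1:12]
  for (s in pool) {
    expect_equal(unname(pred[s]),
                 par$b1[[s]] * sum(as.vector(B)[near][pos$species[near] == s]))
  }
})

test_that("the stand map agrees with the single-pixel path on a sub-window", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 42)
  lay <- make_layout(pool, "random", seed = 6)
  B <- final_biomass(simulate_growth(lay, truth$growth))
  map <- litterfall_map(lay, B, truth$litterfall)
  g <- standlitter:::stand_pixel_geometry(16, 1, 0.1, 12, 0.05)
  for (i in 40:49) for (j in 70:74) {
    ref <- predict_pixel_litterfall(c(g$centers[j], g$centers[i]), lay, B,
                                    truth$litterfall)
    expect_equal(map$species[i, j, ], ref, tolerance = 1e-10)
  }
  expect_equal(map$total, apply(map$species, c(1, 2), sum))
  expect_true(all(map$species >= 0))
})

test_that("map richness is bounded and exact for monocultures", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 42)
  mono <- grid_layout(matrix("sp1", 16, 16))
  mono$mixture <- "sp1"
  map <- litterfall_map(mono, matrix(120, 16, 16), truth$litterfall)
  expect_true(all(map$richness == 1))

  lay <- make_layout(pool, "random", seed = 8)
  B <- matrix(100, 16, 16)
  m8 <- litterfall_map(lay, B, truth$litterfall)
  expect_true(all(m8$richness >= 1 & m8$richness <= 8))
  expect_true(mean(m8$richness) <= 8)
})

test_that("raising b1 never decreases pixel totals", {
  pool <- species_pool(4)
  truth <- generate_ground_truth(pool, seed = 7)
  lay <- make_layout(pool, "random", seed = 7)
  B <- matrix(100, 16, 16)
  m1 <- litterfall_map(lay, B, truth$litterfall)
  bumped <- truth$litterfall
  bumped$b1 <- bumped$b1 * 1.5
  m2 <- litterfall_map(lay, B, bumped)
  expect_true(all(m2$total >= m1$total - 1e-12))
})

test_that("block planting concentrates litter more than random planting", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 42)
  B <- matrix(100, 16, 16)
  sd_block <- sd(as.vector(litterfall_map(make_layout(pool, "block"), B,
                                          truth$litterfall)$total))
  sd_rand <- sd(as.vector(litterfall_map(make_layout(pool, "random", seed = 3),
                                         B, truth$litterfall)$total))
  expect_gt(sd_block, sd_rand)
})

test_that("least squares recovers litterfall coefficients from clean traps", {
  pool <- species_pool(8)
  truth <- generate_ground_truth(pool, seed = 31)
  ds <- generate_field_dataset(truth, n_pairs = 60, seed = 32,
                               trap_sd_frac = 0, bag_sd_pct = 0)
  fit <- fit_litterfall(ds, method = "ls")
  expect_equal(fit$b1, truth$litterfall$b1, tolerance = 1e-8)
  expect_equal(fit$b2, truth$litterfall$b2, tolerance = 1e-8)
  expect_equal(fit$b3, truth$litterfall$b3, tolerance = 1e-8)
})

test_that("degenerate trap geometry is reported as rank deficiency", {
  # single tree per trap at one fixed distance: sum(1/d) is constant and
  # sum(B/d) proportional to sum(B)
  traps <- list(
    trees = data.frame(trap_id = paste0("t", 1:20), tree_idx = 1,
                       species = "sp1", biomass = seq(50, 240, by = 10),
                       distance_m = 1.5),
    litter = data.frame(trap_id = paste0("t", 1:20), species = "sp1",
                        litter_mass_g = seq(5, 24, by = 1)))
  expect_error(fit_litterfall(traps, method = "ls"), "collinear|rank")
})
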