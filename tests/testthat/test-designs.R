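test_that("mixture permutations enumerate and sample the permutation space", {
  pool <- species_pool(8)
  expect_length(mixture_permutations(pool, 2), 56)
  expect_length(mixture_permutations(species_pool(2), 2), 2)
  expect_setequal(
    vapply(mixture_permutations(species_pool(2), 2), paste, "", collapse = "-"),
    c("sp1-sp2", "sp2-sp1"))

  p1 <- mixture_permutations(pool, 4, count = 1000, seed = 11)
  p2 <- mixture_permutations(pool, 4, count = 1000, seed = 11)
  expect_identical(p1, p2)
  keys <- vapply(p1, paste, "", collapse = "-")
  expect_length(unique(keys), 1000)
  expect_true(all(vapply(p1, function(m) anyDuplicated(m) == 0, TRUE)))

  expect_error(mixture_permutations(pool, 2, count = 100), "56")
})

test_that("every template layout holds equal species abundance", {
  pool <- species_pool(8)
  for (r in c(2, 4, 8)) {
    mix <- pool[seq_len(r)]
    for (d in c("block", "miniblock", "double_line", "single_line", "random")) {
      lay <- make_layout(mix, d, seed = 5)
      counts <- table(lay$grid)
      expect_identical(sort(names(counts)), sort(mix))
      expect_true(all(counts == 256 / r),
                  label = sprintf("%s richness %d equal abundance", d, r))
    }
  }
  expect_error(make_layout(paste0("s", 1:3), "random"), "equal abundance")
})

test_that("template geometries match their definitions", {
  pool <- species_pool(8)
  # single line: columns cycle the permutation order
  sl <- make_layout(pool, "single_line")
  for (cc in 1:16) expect_true(all(sl$grid[, cc] == pool[(cc - 1) %% 8 + 1]))
  # block for 2 species: two 8 x 16 halves
  bl2 <- make_layout(pool[1:2], "block")
  expect_true(all(bl2$grid[1:8, ] == "sp1") && all(bl2$grid[9:16, ] == "sp2"))
  # double line: two adjacent columns per species
  dl <- make_layout(pool, "double_line")
  for (cc in 1:16) {
    expect_true(all(dl$grid[, cc] == pool[(ceiling(cc / 2) - 1) %% 8 + 1]))
  }
  # random: seed changes arrangement, not composition
  r1 <- make_layout(pool, "random", seed = 1)
  r2 <- make_layout(pool, "random", seed = 2)
  expect_false(identical(r1$grid, r2$grid))
  expect_identical(table(r1$grid), table(r2$grid))
})

test_that("heterogeneity is zero for monocultures and balanced toy grids", {
  mono <- grid_layout(matrix("sp1", 16, 16))
  expect_equal(heterogeneity(mono)$H, 0)
  expect_equal(heterogeneity(mono, neighborhood("moore"))$H, 0)
  # 2 x 2 checkerboard under full (Moore) adjacency: N(i) = 1 = E[X_i]
  cb <- grid_layout(matrix(c("a", "b", "b", "a"), 2, 2))
  hs <- heterogeneity(cb, neighborhood("moore"))
  expect_true(all(hs$N == 1))
  expect_true(all(hs$E == 1))
  expect_equal(hs$H, 0)
})

test_that("heterogeneity matches the brute-force pair-loop oracle", {
  pool <- species_pool(8)
  for (i in 1:8) {
    lay <- make_layout(pool, "random", seed = 100 + i)
    expect_equal(heterogeneity(lay)$H, brute_H(lay, "rook"))
    expect_equal(heterogeneity(lay, neighborhood("moore"))$H,
                 brute_H(lay, "moore"))
  }
  # template layouts too, and the heterospecific reading
  bl <- make_layout(pool, "block")
  expect_equal(heterogeneity(bl)$H, brute_H(bl, "rook"))
  expect_equal(heterogeneity(bl, expectation = "heterospecific")$H,
               brute_H(bl, "rook", "heterospecific"))
})

test_that("designs order from clustered to random and H centres on zero", {
  pool <- species_pool(8)
  H <- function(d, s = NULL) heterogeneity(make_layout(pool, d, seed = s))$H
  H_rand <- vapply(1:500, function(i) H("random", i), numeric(1))
  expect_gt(H("block"), H("miniblock"))
  expect_gt(H("miniblock"), H("double_line"))
  expect_gt(H("double_line"), H("single_line"))
  expect_gt(H("single_line"), mean(H_rand))
  # null centring: mean H of random layouts is 0 within 3 MC standard errors
  expect_lt(abs(mean(H_rand)), 3 * sd(H_rand) / sqrt(length(H_rand)))
})

test_that("the block-to-random gradient is monotone and evenly spaced", {
  pool <- species_pool(8)
  grad <- make_heterogeneity_gradient(pool, levels = 8, seed = 17,
                                      n_chains = 10, max_swaps = 1500)
  Hs <- vapply(grad, function(l) l$H, numeric(1))
  expect_equal(Hs[1], heterogeneity(make_layout(pool, "block"))$H)
  expect_true(all(diff(Hs) <= 0))
  targets <- vapply(grad, function(l) l$H_target, numeric(1))
  expect_lt(max(abs(Hs - targets)), 25)
  for (l in grad) expect_true(all(table(l$grid) == 32))
  # two endpoints when levels = 2
  g2 <- make_heterogeneity_gradient(pool, levels = 2, seed = 3,
                                    n_chains = 5, max_swaps = 1500)
  expect_equal(g2[[1]]$H, Hs[1])
  expect_lt(abs(g2[[2]]$H), 60)
})

test_that("layouts round-trip through CSV plus JSON sidecar", {
  lay <- make_layout(species_pool(4), "miniblock")
  path <- file.path(tempdir(), "layout.csv")
  write_layout(lay, path)
  back <- read_layout(path)
  expect_identical(back$grid, lay$grid)
  expect_identical(back$design, lay$design)
  expect_identical(back$mixture, lay$mixture)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$H, heterogeneity(lay)$H)
})
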