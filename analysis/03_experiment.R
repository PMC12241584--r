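#!/usr/bin/env Rscript
# The factorial planting experiment, scaled down.
#
# Simulates the full pipeline (layouts -> tree growth -> litterfall map ->
# decomposition maps -> stand summaries) for a scaled-down version of the
# factorial experiment: 20 mixture permutations (7 two-, 7 four- and 6
# eight-species) x (4 gradient levels + mini-block + double line + single
# line). The full-size experiment (56 + 1000 + 1000 permutations x 11
# designs = 22,308 stands) uses the same code path; see the vignette.

library(standlitter)

dir.create("results", showWarnings = FALSE)
seed <- 11L

pool <- species_pool(8)
truth <- generate_ground_truth(pool, seed = 42L)
cfg <- experiment_config(
  pool = pool,
  richness = c(2, 4, 8),
  n_perm = list(7L, 7L, 6L),
  designs = c("gradient", "miniblock", "double_line", "single_line"),
  gradient_levels = 4L,
  years = 10L,
  seed = seed,
  params = list(growth = truth$growth,
                litterfall = truth$litterfall,
                decomp = list(C = truth$decomp_C, N = truth$decomp_N)))

t0 <- Sys.time()
tab <- run_experiment(cfg, progress = FALSE)
cat(sprintf("Simulated %d stands in %.1f min (%d failed)\n", nrow(tab),
            as.numeric(difftime(Sys.time(), t0, units = "mins")),
            sum(!is.na(tab$error))))
write.csv(tab, "results/stand_summaries.csv", row.names = FALSE)

e8 <- tab[tab$richness == 8 & is.na(tab$error), ]
lo <- e8[e8$H > median(e8$H), ]   # clustered half (block-like)
hi <- e8[e8$H <= median(e8$H), ]  # mixed half (random-like)
cat("\nEight-species stands, clustered vs spatially mixed halves:\n")
cat(sprintf("  litterfall SD between pixels: %.1f vs %.1f g/m2\n",
            mean(lo$sd_litterfall), mean(hi$sd_litterfall)))
cat(sprintf("  mean pixel litter richness:   %.2f vs %.2f species\n",
            mean(lo$mean_pixel_richness), mean(hi$mean_pixel_richness)))
cat(sprintf("  mean carbon loss rate:        %.1f vs %.1f %%\n",
            mean(lo$mean_D_C), mean(hi$mean_D_C)))
cat(sprintf("  mean carbon loss:             %.2f vs %.2f g/m2\n",
            mean(lo$total_loss_C), mean(hi$total_loss_C)))
cat("\nSpatially mixed stands spread litter more evenly, raise pixel litter\n")
cat("richness and decompose faster, as expected from the model structure.\n")
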