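#!/usr/bin/env Rscript
# Plantation designs and their spatial heterogeneity.
#
# Builds the template planting designs (block, mini-block, double line,
# single line, random) and the 8-level block-to-random gradient for an
# eight-species mixture, scores each against the hypergeometric null, and
# reports how much of the block-to-random heterogeneity gap the line
# designs close.

library(standlitter)

dir.create("results", showWarnings = FALSE)
dir.create("results/layouts", showWarnings = FALSE)
seed <- 1L

pool <- species_pool(8)
templates <- c("block", "miniblock", "double_line", "single_line", "random")
rows <- lapply(templates, function(d) {
  lay <- make_layout(pool, d, seed = seed)
  write_layout(lay, file.path("results/layouts", paste0(d, ".csv")))
  data.frame(design = d, H = heterogeneity(lay)$H)
})
grad <- make_heterogeneity_gradient(pool, levels = 8, seed = seed)
rows <- c(rows, lapply(grad, function(l) {
  write_layout(l, file.path("results/layouts", paste0(l$design, ".csv")))
  data.frame(design = l$design, H = l$H)
}))
tab <- do.call(rbind, rows)

H_block <- tab$H[tab$design == "block"]
tab$gap_closed_pct <- 100 * (H_block - tab$H) / H_block
write.csv(tab, "results/designs_H.csv", row.names = FALSE)

cat("Heterogeneity H per design (eight-species mixture, 16 x 16 grid):\n")
print(tab, row.names = FALSE, digits = 4)
cat(sprintf("\nSingle lines close %.1f%% of the block-to-random gap;",
            tab$gap_closed_pct[tab$design == "single_line"]))
cat(sprintf(" double lines close %.1f%%.\n",
            tab$gap_closed_pct[tab$design == "double_line"]))
cat("Gradient H values are evenly spaced from block to the random null (~0).\n")
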