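#!/usr/bin/env Rscript
# Field-data emulation and model fitting.
#
# Generates a synthetic field campaign (180 tree pairs with litter traps and
# paired litterbags) from a known ground truth, writes the CSV files, then
# fits the litterfall and decomposition models by least squares and by MCMC
# and tabulates how well the known coefficients are recovered.

library(standlitter)

dir.create("results", showWarnings = FALSE)
seed <- 101L

pool <- species_pool(8)
truth <- generate_ground_truth(pool, seed = seed)
ds <- generate_field_dataset(truth, n_pairs = 180, seed = seed + 101L)
write_field_dataset(ds, "results/field_data")
cat(sprintf("Wrote %d trap records and %d litterbag rows to results/field_data/\n",
            nrow(ds$litter), nrow(ds$bags)))

recovery <- function(est, tru, model, term) {
  data.frame(model = model, term = term, species = names(tru),
             truth = unname(tru), estimate = unname(est),
             rel_error = unname(abs(est - tru) / abs(tru)))
}

lf_ls <- fit_litterfall(ds, method = "ls")
lf_mc <- fit_litterfall(ds, method = "bayes", seed = seed)
dc_ls <- fit_decomposition(ds$bags, "C", method = "ls")
dc_mc <- fit_decomposition(ds$bags, "C", method = "bayes", seed = seed)

tab <- rbind(
  recovery(lf_ls$b1, truth$litterfall$b1, "litterfall_ls", "b1"),
  recovery(lf_ls$b2, truth$litterfall$b2, "litterfall_ls", "b2"),
  recovery(lf_ls$b3, truth$litterfall$b3, "litterfall_ls", "b3"),
  recovery(lf_mc$b1, truth$litterfall$b1, "litterfall_mcmc", "b1"),
  recovery(lf_mc$b2, truth$litterfall$b2, "litterfall_mcmc", "b2"),
  recovery(lf_mc$b3, truth$litterfall$b3, "litterfall_mcmc", "b3"),
  recovery(dc_ls$beta, truth$decomp_C$beta, "decomposition_ls", "beta"),
  recovery(dc_ls$alpha, truth$decomp_C$alpha, "decomposition_ls", "alpha"),
  recovery(dc_mc$beta, truth$decomp_C$beta, "decomposition_mcmc", "beta"),
  recovery(dc_mc$alpha, truth$decomp_C$alpha, "decomposition_mcmc", "alpha"))
write.csv(tab, "results/fit_recovery.csv", row.names = FALSE)

cat("\nMedian / max relative error by model and term:\n")
agg <- aggregate(rel_error ~ model + term, tab,
                 function(x) c(median = median(x), max = max(x)))
print(cbind(agg[1:2], round(agg$rel_error, 3)), row.names = FALSE)
cat("\nIdentity terms (litterfall b2, decomposition beta) recover well;\n")
cat("the collinear biomass terms (b1, b3) and small diversity terms carry\n")
cat("wide uncertainty at n = 180 - see the package vignette for why this\n")
cat("is a property of the field design, not of the fitting code.\n")
if (!is.null(lf_mc$uncertainty))
  cat(sprintf("Max split R-hat (litterfall MCMC): %.3f\n",
              max(lf_mc$uncertainty$rhat)))
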