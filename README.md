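# standlitter

Spatially explicit simulation of tree planting designs and their litter
dynamics.

When a mixed forest is planted, someone must decide *where* each species
goes: blocks of one species are easy to manage, fully random mixtures
maximise species mixing, and lines sit in between. `standlitter` is for
ecologists and forest scientists who want to quantify what that choice does
to stand functioning. It simulates 16 x 16-tree stands (1 m spacing,
225 m^2) planted with 2-, 4- or 8-species mixtures in block, mini-block,
double-line, single-line, random, or intermediate-gradient designs, and
chains four models over each stand:

1. **Spatial heterogeneity.** Each layout is scored against a hypergeometric
   null: with tree *i* having *n_i* neighbours and *M_s* planted
   conspecifics among *T* = 256 trees,

       H = sum_i [ N(i) - n_i (M_s - 1) / (T - 1) ]

   where *N(i)* counts conspecific neighbours. H ~ 0 means random mixing;
   large H means clustering.
2. **Tree growth.** B_{t+1,i} - B_{t,i} = beta_s B_{t,i}^theta +
   sum_j alpha_{s(i),s(j)} B_{t,j}^b over the eight neighbouring trees,
   10 annual steps from B_0 = 100.
3. **Litterfall.** Per-species litter mass at every 0.1 x 0.1 m pixel:
   L_i = b_1i sum(B_ij) + b_2i sum(1/d_ij) + b_3i sum(B_ij/d_ij) over the 12
   nearest trees, fitted to litter-trap records by least squares or MCMC.
4. **Decomposition.** Diversity-interaction model for element loss (%):
   D = sum_i beta_i P_i + sum_{i<j} (alpha_i + alpha_j) P_i P_j + b_4 L +
   b_5 S, fitted to litterbag records, then applied pixel-wise.

A synthetic field-campaign generator (180 tree pairs with litter traps and
paired litterbags, known ground-truth coefficients) makes every fitting
stage testable without external data. Stand summaries feed a
`response ~ richness * H` model testing whether species-richness effects
strengthen with spatial mixing.

## Worked example

```r
library(standlitter)

pool <- species_pool(8)                       # sp1 ... sp8
lay  <- make_layout(pool, "single_line")
heterogeneity(lay)
#> <heterogeneity> H = 363.29 (rook adjacency, conspecific expectation)

heterogeneity(make_layout(pool, "block"))$H   # 715.29: maximal clustering
heterogeneity(make_layout(pool, "random", seed = 1))$H  # -20.71: ~ null

truth <- generate_ground_truth(pool, seed = 42)     # known coefficients
field <- simulate_growth(lay, truth$growth)         # 16 x 16 x 11 biomass
lmap  <- litterfall_map(lay, final_biomass(field), truth$litterfall)
dmap  <- decomposition_map(lmap, truth$decomp_C)
summarize_stand(field, lmap, list(C = dmap), lay)[, 4:9]
#>          H mean_biomass mean_litterfall sd_litterfall mean_pixel_richness mean_D_C
#> 1 363.2941     143.1077        241.2762      47.51794            3.931022 50.75109
```

Single lines score H = 363 against 715 for blocks: one move from blocks to
lines already closes about half of the distance to random planting. The
stand summary says this layout sheds ~241 g/m^2 of litter with a
between-pixel SD of ~48 g/m^2, an average of 3.9 litter species per
square-decimetre pixel, and a mean carbon loss rate of 50.8%.

The numbered scripts under `analysis/` run the full workflow: `01_designs.R`
(design heterogeneity table), `02_synthetic_fits.R` (synthetic field
campaign, least-squares and MCMC fits, coefficient-recovery table),
`03_experiment.R` (a 140-stand scaled-down factorial experiment) and
`04_interactions.R` (richness x heterogeneity ANOVA table). Each writes its
tables under `results/`.

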