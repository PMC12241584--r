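Package: standlitter
Title: Spatially Explicit Simulation of Tree Planting Designs, Litterfall and Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and analyse simulated forest plantations on a
    16 x 16 planting grid. Generates species-mixture permutations and planting
    layouts spanning a gradient of spatial heterogeneity (blocks, mini-blocks,
    double lines, single lines, random), scores layouts against a
    hypergeometric null model of conspecific neighbourhood, simulates
    individual tree growth with species-specific pairwise neighbour
    interactions, predicts per-decimetre litterfall from a distance-decay
    model and litter decomposition from an additive diversity-interaction
    model, and summarises stand-level biomass, litterfall evenness and carbon
    and nitrogen loss. Includes a synthetic field-data generator with known
    ground truth so every fitting stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
RoxygenNote: 7.3.3
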