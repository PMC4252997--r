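Package: MicrobiomeStability
Title: Temporal Variability Analysis of Longitudinal Microbiome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the temporal stability of host-associated microbial
    communities sampled repeatedly through time. From a phylotype count
    table, a rooted phylogeny and per-sample metadata it computes
    per-individual variability scores (coefficient of variation of alpha
    diversity; median intra-individual unweighted and weighted UniFrac),
    quartile-based stability classes, phylotype-sharing (occupancy) curves,
    family-level enrichment across stability classes, antibiotic-effect
    tests (population-level Mann-Whitney and a within-individual Monte
    Carlo rank t-test), time-decay Mantel tests, diversity-stability
    models, and backward-stepwise Gaussian GLMs that predict variability
    from host covariates. A Dirichlet-multinomial cohort simulator with
    tunable per-subject turnover generates longitudinal communities with
    known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    car
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
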