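Package: envgp
Title: Enviromic Genomic Prediction with Multi-Kernel G-by-E Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-environment genomic prediction for plant breeding that
    combines genomic relationship kernels (additive, dominance, additive-by-
    additive epistatic) with environmental relationship kernels built from
    daily weather records, and models genotype-by-environment interaction
    through Hadamard-product covariance structures. Provides a Bayesian
    Gibbs sampler for the kernel mixed models, the four cross-validation
    geometries used to benchmark sparse-testing designs (cv1-cv4), windowed
    Weir-Cockerham Fst, genomic deduplication and BLUE estimation,
    G-by-E-pattern environment clustering with gradient-boosted environment-
    variable importance, and selection of enviromically adapted genotypes.
    Ships a synthetic-data generator that emulates elite line/hybrid breeding
    populations and multi-site weather so every method is testable without
    proprietary trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
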