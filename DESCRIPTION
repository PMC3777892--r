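Package: spatgen
Title: Spatial Population Genetics: Admixture Range Classification and
    Residual Isolation-by-Distance Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based landscape genetics from multilocus
    microsatellite genotypes and sample coordinates. Interpolates admixture
    membership coefficients onto a regular grid by inverse-distance
    weighting and classifies every grid point into core / probable /
    outside range per genetic group against a resampling null. Detects
    migration corridors, barriers and contact zones by interpolating
    residuals of an isolation-by-distance fit at sample-pair midpoints
    within distance classes, with permutation significance (the DResD
    procedure). Includes the genotype likelihood ratio distance (D_LR),
    proportion-of-shared-alleles distance, Weir-Cockerham F-statistics,
    rarefied allelic richness, Mantel tests, readers for STRUCTURE and
    GenePop formats, and a seeded simulator of spatially structured
    genotype datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
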