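Package: traitgrad
Title: Trait Gradients, Hydraulic Conductivity and Phenotypic Integration
    Across Fog-Forest Moisture Zones
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intraspecific functional-trait variation
    across the steep soil-moisture gradients of fog-dependent forest
    patches.  Computes stem hydraulic conductivity (K_h), sapwood-specific
    conductivity (K_s) and percent loss of conductivity (PLC) from balance
    flow logs; compares trait variability between moisture zones with a
    bootstrap test for equality of coefficients of variation, including
    Bonferroni-adjusted pairwise comparisons and compact letter displays;
    and quantifies phenotypic integration as the variance of the
    eigenvalues of trait correlation matrices, with percentile bootstrap
    confidence intervals and permutation tests of between-zone matrix
    similarity.  A Gaussian-copula synthetic trait generator with
    lognormal marginals reproduces the windward/core/leeward sampling
    design so that every stage of the pipeline is testable without field
    data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
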