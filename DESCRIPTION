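Package: micosim
Title: Copula-Based Simulation of Realistic Microbiome Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-step generative model to a template microbiome count
    table and simulates new count tables that reproduce its sparsity,
    marginal distributions, and taxon-taxon correlation structure. Step one
    models presence-absence through a probit threshold model with a smoothed
    tetrachoric correlation matrix; step two fills the non-zero cells through
    a Gaussian copula whose marginals are either the empirical non-zero
    relative abundances (nonparametric mode) or fitted generalized gamma
    distributions on the inverse-abundance scale (parametric mode, estimated
    by moment matching plus a profile likelihood for the shape). Fitted
    models can be modified in a controlled way (library sizes, mean relative
    abundances, zero proportions, sample size, binary covariate effects on
    selected taxa) to build benchmark datasets for differential-abundance
    methods, and a diagnostics suite (alpha diversity, Jaccard and
    Bray-Curtis distances, beta dispersion, PERMANOVA) compares simulated
    data against the template.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    flexsurv,
    mvtnorm,
    vegan,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    biomformat
Config/testthat/edition: 3
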