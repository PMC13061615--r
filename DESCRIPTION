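Package: spatcog
Title: Spatial Mapping of Air Pollution-Cognition Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate spatial regression for urban cohort data on a
    kilometre-resolution grid. Builds a Gaussian-kernel sample-concentration
    response for each participant, fits a shared design with
    cognition-by-exposure interaction terms at every grid cell, thresholds the
    resulting t-maps with a voxel-level family-wise error correction based on
    Gaussian random field theory, and summarises significant regions by the
    signs of their interaction and individual effects. Includes a non-spatial
    Bayesian ridge-regression comparator fitted by Gibbs sampling, a synthetic
    urban cohort generator with planted interaction effects for validation,
    and a sensitivity suite over kernel sizes, analysis windows and non-mover
    subcohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
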