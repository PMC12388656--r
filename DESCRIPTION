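Package: assemblyscape
Title: Depth-Stratified Microbial Community Assembly Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for inferring the ecological processes
    that assemble soil microbial communities across depth layers. Implements
    phylogenetic null models (beta-mean-nearest-taxon distance and its
    standardized index betaNTI), the Bray-Curtis-based Raup-Crick metric,
    five-way assembly-process classification, Sloan's neutral community
    model, genus-level co-occurrence and taxon-environment correlation
    networks with topology summaries, distance-decay regression, multiple
    regression on distance matrices, and partial least squares path
    modeling. Ships a synthetic-data generator that produces phylogenies,
    phylogenetically conserved niches, depth-stratified environments and
    communities under named assembly regimes, so every inference stage can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
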