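Package: msatABC
Title: Microsatellite Population Genetics and Coalescent ABC Demographic
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diploid codominant microsatellite data: genepop
    input/output, multilocus genotype (MLG) identification and clonal
    lineage (MLL) collapsing, per-population diversity statistics
    (unbiased gene diversity, rarefied allelic richness, Weir-Cockerham
    F(IS)) and pairwise F(ST) (theta) with permutation tests and
    Bonferroni-adjusted nominal levels, factorial correspondence
    analysis of allele counts, and approximate Bayesian computation
    (ABC) over coalescent divergence scenarios with a generalized
    stepwise mutation model: reference-table simulation, rejection,
    scenario choice by direct and multinomial-logistic estimates,
    local-linear parameter posteriors, and posterior predictive checks.
    Includes a synthetic-data generator producing study-shaped data sets
    with known truth (injected clone pairs and null alleles) and a
    pipeline driver orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
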