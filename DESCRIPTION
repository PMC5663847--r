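Package: finpop
Title: Population Structure, Demographic History and Effective Size of
    Fragmented Cetacean Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic inference for small, fragmented populations
    typed at microsatellite loci and a maternally inherited control-region
    sequence, built around the Yangtze finless porpoise study design.
    Provides diversity and differentiation statistics (expected and observed
    heterozygosity, Weir-Cockerham F-statistics with permutation tests,
    rarefied and private allelic richness, the Garza-Williamson M-ratio with
    a coalescent null test, haplotype and nucleotide diversity, Watterson's
    theta, Tajima's D, Hudson F_ST and the Snn nearest-neighbour test),
    contemporary effective population size from linkage disequilibrium
    (Burrows composite disequilibrium with the Waples bias correction), a
    multi-population coalescent simulator with generalized stepwise
    microsatellite mutation and finite-sites sequence mutation, a
    declarative demographic-scenario language with priors, and a nested
    approximate Bayesian computation workflow: reference-table simulation,
    rejection, model choice by LDA-logistic regression and random forest,
    error-rate calibration, local-linear parameter estimation and posterior
    predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    nnet,
    randomForest,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
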