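Package: msatABC
Title: Approximate Bayesian Computation for Microsatellite Demographic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-free (ABC) inference of demographic history from
    multi-locus microsatellite genotypes. Provides an exact structured
    coalescent simulator with exponential growth, population splits and
    migration, a symmetric generalized stepwise mutation model with
    geometric step sizes, the classical microsatellite summary statistics
    (expected heterozygosity, repeat-number variance, allele counts,
    modal allele frequency, singletons, pairwise Weir-Cockerham F_ST),
    rejection sampling with local-linear regression adjustment, model
    choice via acceptance-ratio Bayes factor approximations, and
    posterior predictive checks with PCA summaries. Built for dating
    population expansions and comparing divergence topologies, e.g. for
    the Bantu-speaker expansion in sub-Saharan Africa, and ships a fully
    seeded pseudo-observed-data generator so the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
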