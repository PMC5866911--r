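Package: heatfeed
Title: Heat-Stress Feeding-Behaviour Phenotypes and Bayesian
    Whole-Genome Regression in Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies changes in pig feeding activity under heat stress
    and maps the genetics of that response. Computes the hourly
    temperature-humidity index (THI) and classifies days into the four
    heat-load categories; derives standardized pairwise-THI
    feeding-behaviour traits from RFID feeder ping counts; applies minor
    allele frequency and map-position marker quality control; fits Bayes-C
    and Bayes-Cpi whole-genome regression models by Gibbs sampling, with
    genomic heritability summaries and a 1-Mb window decomposition of
    genomic variance; and tests gene-ontology term over- and
    under-representation with a binomial test and Bonferroni correction.
    Includes a simulator generating weather series, pedigreed genotypes
    with planted QTL, and overdispersed daily feeder counts with known
    variance components, so the whole pipeline can be exercised against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    graphics,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
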