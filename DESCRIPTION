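Package: kradom
Title: Additive and Dominance Genetic Analysis for Crossbred Chicken Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based quantitative-genetic analysis of crossbred
    (sire line x dam line -> F1) chicken breeding data. Builds numerator
    (additive, A) and dominance (D) relationship matrices by the tabular
    method, fits the additive-plus-dominance animal model y = Xb + Za + Wd + e
    by restricted maximum likelihood (EM iterations with average-information
    acceleration), solves Henderson's mixed-model equations for additive and
    dominance BLUPs, derives heritability and the dominance ratio with
    standard errors, computes midparent heterosis from least-square means,
    and tests marker-genotype effects on any per-animal quantity with
    Tukey-Kramer mean comparisons. A seeded crossbreeding simulator with
    known ground truth (pedigree, Mendelian marker transmission, A/D
    structured genetic effects, phenotypes) makes the whole chain testable
    without external data; a Monte-Carlo gene-dropping kernel serves as an
    independent oracle for the relationship matrices.
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
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
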