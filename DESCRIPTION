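Package: tetrasel
Title: Training Set Construction for Genomic Prediction in Autotetraploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build and evaluate genomic-prediction training sets for
    autotetraploid crops genotyped with biallelic SNP allele dosages (0-4).
    Implements dosage-aware genetic distance and similarity measures (Nei,
    Euclidean, Jaccard, Kosman-Leonard), the VanRaden additive genomic
    relationship matrix on dosage data, four training-set samplers (simple
    random, stratified proportional, genetic-distance radial exclusion, and
    CDmean exchange optimisation), three whole-genome regression models
    (GBLUP and Gaussian-kernel RKHS by spectral REML, BayesC-pi by Gibbs
    sampling), and two cross-validation designs (training-validation and
    training-test) with factorial ANOVA of Fisher-z transformed prediction
    accuracies. A synthetic tetraploid diversity-panel generator
    (Balding-Nichols allele frequencies, binomial dosages, configurable trait
    architectures) makes the full workflow runnable and testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    car,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    vegan
Config/testthat/edition: 3
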