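Package: episketch
Title: Exhaustive Pairwise Epistasis Scans by Sketched Ridge Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive two-dimensional genome scans for epistasis: a
    sketch-compressed regularized least-squares estimator over all pairwise
    SNP interaction columns (the face-splitting product of the genotype
    matrix with itself), with block-wise solving, sketch averaging, and
    top-N* sparse support selection. Includes a genotype/phenotype simulator
    with controlled narrow-sense heritability and Marchini-type two-locus
    interaction models, minor (interaction) allele frequency filtering,
    truth-based recall metrics, principal-component-regression heritability
    curves, max-pooled interaction-map pyramids for visualization, a
    two-locus haplogroup decomposition, and a phenotype-classification
    harness comparing true against random interaction features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    nnet,
    e1071,
    ranger,
    glmnet,
    optparse
Config/testthat/edition: 3
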