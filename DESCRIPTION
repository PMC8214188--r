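Package: depthDGE
Title: Sequencing-Depth Robustness Benchmarking for Differential
    Expression Pipelines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks the robustness of two-group differential gene
    expression (DGE) pipelines to reduced sequencing depth. Simulates
    negative-binomial count matrices with known differential-expression
    structure, titrates depth by seeded binomial thinning over a fraction
    grid, runs interchangeable simplified DGE engines (exact
    negative-binomial test, Wald test, precision-weighted moderated t,
    non-parametric noise-cloud posterior, empirical-Bayes
    negative-binomial mixture), and scores depth robustness via relative
    false discovery rate, percentage change and miss-detection rate,
    DEG-set concordance, and a population-of-slopes comparison using the
    tie-corrected Friedman test with Conover and Nemenyi post hocs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    DESeq2,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialExpression, Normalization, Sequencing,
    GeneExpression, Software
RoxygenNote: 7.3.3
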