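Package: gtdr
Title: Interpretable Drug Response Prediction on Drug-Cell-Gene
    Heterogeneous Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts binary drug sensitivity of cancer cell lines from a
    heterogeneous graph connecting drugs, cell lines and genes, using stacked
    multi-head graph-attention (Graph Transformer) layers trained end-to-end
    with binary cross-entropy. Inputs are a continuous IC50 response matrix,
    a gene expression matrix, drug structures (SMILES or precomputed
    fingerprints) and known drug-target interactions. Beyond prediction, the
    learned attention coefficients are aggregated into ranked drug-gene
    associations, classified against known interactions, and carried into
    hypergeometric over-representation analysis of gene-set collections.
    Includes two evaluation protocols (masked-entry cross-validation and
    leave-one-out cold start), a seeded synthetic-cohort generator with a
    planted drug-target-response mechanism, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
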