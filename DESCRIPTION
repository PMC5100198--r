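Package: pleiosem
Title: Sparse Structural Equation Models for Genotype-Phenotype Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint inference of genetic architecture and causal phenotype
    networks from multi-phenotype genotype data using sparse structural
    equation models. Implements L1-penalized two-stage least squares fitted
    by an ADMM solver, functional principal component representation of
    per-gene genotype profiles for rare-variant (sequencing) data, chi-square
    tests for path coefficients with multiplicity adjustment and stability
    selection, decomposition of genetic effects into direct, indirect, total
    and marginal components, and a simulation harness that measures power of
    detection and false discovery rate of network recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
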