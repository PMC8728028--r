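Package: utrmpra
Title: Analysis of Massively Parallel Reporter Assays of 3' UTR Regulatory
    Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for analysing massively parallel reporter assay
    (MPRA) data on human 3' UTR sequence fragments. Provides scanners for
    AU-rich elements (AREs, periodic AUUUA repeats classified by length and
    registration) and constitutive decay elements (CDEs, UUCYRYGAA stem-loops
    classified by lower-stem length), designed-mutant generation, clone-level
    DNA/RNA count quantification of steady-state expression and mRNA
    stability, polynomial GC-content residualization with leave-one-out order
    selection, variance-decomposition estimates of sequence explainability
    (b-squared), and leave-one-chromosome-out benchmarking of ARE activity
    predictors including lasso k-mer regression. A synthetic-data module
    generates barcoded clone count libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
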