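Package: cellsig
Title: Brain Cell Type Expression Signatures and Proportion Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives brain cell-type association signatures (enrichment,
    specificity, and absolute expression) from labeled RNA-seq count
    matrices using shrunken log2 fold changes and negative-binomial
    likelihood-ratio tests; aggregates per-dataset signatures into
    cross-dataset consensus marker rankings; quantifies overlap between
    gene sets and coexpression modules (fold enrichment, multi-set
    intersection tests, Fisher's exact enrichment); and estimates
    surrogate cell-type proportion variables from bulk expression via
    singular value decomposition of marker-gene submatrices, with
    residualization to remove cell-composition effects. Includes seeded
    negative-binomial simulators of single-cell-like matrices with
    planted markers and of Dirichlet-mixed bulk profiles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    limma,
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
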