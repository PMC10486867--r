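Package: gemtree
Title: Nested Tree-Structured Gene Co-Expression Modules from Single-Cell
    UMI Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes sparse single-cell UMI count matrices into
    hierarchically organized gene co-expressing modules (GEMs): topics laid
    out on a preset tree so that high levels carry broad, shared
    transcriptomic programs and leaves carry specialized ones. Provides 10x
    Genomics triplet-format input/output with standard quality-control
    filtering, a recursive L1 k-medians tree initialization with
    information-breaking residuals, penalized EM / stochastic variational
    training of the finite-tree nested topic model with a depth-switching
    parameter and transfer-learning warm starts, fold-in inference for
    held-out cells, evaluation by held-out perplexity and pointwise-mutual-
    information topic coherence, cosine-similarity comparison of module
    top-gene lists against marker sets, GMT gene-set export, and seeded
    synthetic-data generators (splatter-style count marginals and planted
    tree-structured corpora with known ground truth).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
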