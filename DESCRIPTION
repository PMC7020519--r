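Package: cycleGRN
Title: Recovering Cell-Cycle Expression from Gene Regulatory Network Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying how transcription-factor (TF) to target-gene
    interactions explain the timing of cell-cycle gene expression in budding
    yeast. Provides a gene-regulatory-network (GRN) data model with edge-list
    input/output and cross-dataset comparison statistics (interaction overlap,
    overlap coefficients, degree correlation, uniqueness, degree-preserving
    randomization nulls with z-tests); feed-forward-loop (FFL) motif
    enumeration with mean-connectivity expectation statistics; a balanced
    subsampling ensemble protocol around a linear support vector machine with
    (C, R) grid search, averaged-score AUC-ROC and weight-based feature
    importance; percentile importance subsets and importance subnetwork
    extraction; a linear ordinary-differential-equation model of FFL
    transcription dynamics with closed-form solution, maximum-likelihood
    fitting and an acceptance filter; Fisher exact-test enrichment with
    Benjamini-Hochberg correction; and a synthetic-data generator that
    emulates the statistical structure the analyses assume, so the whole
    pipeline is exercisable end-to-end without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    e1071,
    igraph,
    deSolve,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
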