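Package: netsilent
Title: Network-Based Integration of Mutation and Expression Data to
    Prioritize Silent Cancer Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates per-sample somatic mutation and differential
    expression profiles over a weighted protein-protein interaction
    network to prioritize "silent player" genes: genes that are neither
    frequently mutated nor differentially expressed themselves, but lie
    close in the network to both kinds of signal across tumor samples.
    Provides Laplacian-normalized network propagation at sample-specific
    resolution, a thirteen-feature per-gene consolidation of raw and
    propagated signals, logistic-regression scoring with greedy AIC
    step-down, evaluation utilities (ROC/AUC, Kolmogorov-Smirnov feature
    comparisons, hypergeometric enrichment, log-rank survival
    stratification), a synthetic-cohort generator with planted causal
    modules for offline testing, and a command-line interface wiring the
    pieces into a single workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    Matrix,
    methods,
    optparse,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
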