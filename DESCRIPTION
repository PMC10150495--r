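Package: xenohet
Title: Species-Stratified Analysis of Xenograft Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing spatial transcriptomics sections of
    patient-derived orthotopic xenografts profiled against a hybrid
    human+mouse reference. Classifies array spots by species from summed
    normalised expression with per-sample cutoffs, quantifies clustering
    heterogeneity across a Louvain resolution scan (Shannon entropy,
    Simpson index, connectivity index, modularity, cluster trees,
    Jensen-Shannon divergence), maps per-spot gene-set activity with the
    parametric PAGE statistic, runs species-stratified pseudobulk
    differential expression with TMM size factors and a fold-change
    threshold test, annotates spots by dominant reference cell type via
    Spearman correlation, and tests cell-type enrichment at the
    tumour-brain interface. Ships a seeded synthetic-section generator
    emulating a two-species tumour/interface/cerebellum geometry so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    edgeR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    limma,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
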