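Package: pericyteMarkers
Title: Cross-Tissue Pericyte Marker Discovery from Single-Cell and Spatial
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for discovering tissue-specific pericyte
    marker genes from gene-by-cell count matrices: log-normalization,
    variance-stabilizing-transformation selection of highly variable genes,
    PCA, shared-nearest-neighbor Louvain clustering, dual canonical-marker
    gating of stringent pericytes, Wilcoxon rank-sum differential expression
    with percent-expressed specificity filters (pct1/pct2/pct3), cross-tissue
    marker set comparison, pre-ranked gene set enrichment analysis with
    permutation false discovery rates, and spatial-spot co-localization.
    Includes a synthetic-data generator that plants ground-truth marker
    genes, a confusable mural population and a vessel-like spatial section,
    so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    fgsea,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
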