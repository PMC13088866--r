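Package: scTubule
Title: Metabolic State and Trajectory Analysis of Tubular Epithelial
    Cells in Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for single-cell RNA-seq of
    diseased kidney with a focus on proximal tubule heterogeneity:
    quality control and normalization, variable-gene selection, PCA with
    elbow-based dimensionality choice, graph-based clustering and UMAP,
    marker- and reference-based cell-type annotation, one-vs-rest
    Wilcoxon differential expression, additive glycolysis/OXPHOS pathway
    scoring with a four-state metabolic classification, graph-distance
    pseudotime with per-cluster stretching and gene dynamics, a per-gene
    importance-versus-conservation functional landscape, ligand-receptor
    coexpression scoring with a permutation null, and a random-forest
    cell-state classifier with cross-validated ROC/PR evaluation. A
    kidney-like count-matrix simulator with planted cell types,
    metabolic programs and an injury pseudotime gradient provides ground
    truth for every stage.
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
    igraph,
    irlba,
    uwot,
    ranger,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
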