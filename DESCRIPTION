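Package: cardiomap
Title: Single-Nucleus RNA-Seq QC, Clustering, and Pseudobulk Differential
    Expression for Failing-Heart Cell Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds quality-controlled cell maps from single-nucleus RNA-seq
    of human myocardium and tests condition effects at patient-level
    replication. Implements a cluster-aware interquartile-range QC cascade
    over entropy, mitochondrial fraction, exonic-read fraction and a
    simulated-doublet score; AUC-gated Leiden subclustering with a
    Ward-linkage merge rule; pseudobulk differential expression with
    covariate adjustment and dual-count (raw versus ambient-corrected)
    concordance; a per-gene, per-cell-type ambient-background contamination
    heuristic; and downstream filter cascades for shared and
    disease-specific genes, druggable-genome annotation, Fisher gene-set
    enrichment, probe-pair selectivity and cell-type composition. Ships a
    synthetic-data generator with planted ground truth (cell-type programs,
    ambient contamination, doublets, low-quality nuclei, condition effects)
    used to validate every stage end to end.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, RNASeq, QualityControl, Clustering,
    DifferentialExpression, GeneExpression
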