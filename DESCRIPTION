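Package: consensusGSA
Title: Consensus Gene Set Enrichment for Bulk RNA-seq via the Harmonic
    Mean P-Value
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A downstream analysis pipeline for bulk RNA-seq studies with
    subtle, coordinated expression changes. Transcript abundances are
    aggregated to gene level, lowly expressed genes filtered, libraries
    TMM-normalised, and one factor of unwanted variation estimated from
    negative-control genes (RUVg). Per-gene differential expression uses
    negative-binomial generalised linear models, and gene-set signal is
    assessed by three independent algorithms (a self-contained Monte-Carlo
    rotation test, a competitive test adjusted for inter-gene correlation,
    and preranked GSEA with leading-edge extraction) whose p-values are
    combined per set by the harmonic mean p-value and FDR-adjusted. A
    gene-label permutation experiment validates the consensus, and a
    truth-known negative-binomial simulator emulating a four-genotype
    sibling design makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    MASS,
    withr,
    knitr,
    rmarkdown
biocViews: GeneSetEnrichment, DifferentialExpression, RNASeq,
    Normalization, BatchEffect, Pathways
Config/testthat/edition: 3
RoxygenNote: 7.3.3
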