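Package: cloneTx
Title: Clone-Aware Analysis of Drug-Induced Transcriptomic Reprogramming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clone-aware analysis of drug-induced transcriptional
    reprogramming in serially passaged tumour xenograft time series measured
    with joint single-cell copy-number (DLP-style) and single-cell RNA
    sequencing. The package assigns scRNA-seq cells to copy-number clones
    under a gene-dosage model, classifies differentially expressed genes into
    in-cis and in-trans dosage categories, quantifies treatment-induced,
    repressed and holiday-diverged gene dynamics, runs preranked gene set
    enrichment with permutation-normalised scores, infers simplified
    minimum-spanning-tree lineages with projection pseudotime and gene-module
    clustering, and classifies promoter chromatin status from ChIP/input
    signal. A fully specified synthetic-data generator emulating multi-clone
    copy-number profiles, treatment-shifted clone prevalences and
    dosage-coupled negative-binomial counts makes every stage testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    edgeR,
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
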