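Package: clonevasc
Title: Clonal Lineage Tracing and Single-Cell State Analysis of Cardiac Endothelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of multicolour (Brainbow/Confetti)
    lineage tracing of cardiac endothelial cells and of droplet single-cell
    RNA-seq endothelial state atlases. Provides a calibrated stochastic tissue
    simulator (biased four-colour recombination, spatially contiguous clonal
    expansion, vessel-segment membership, EdU S-phase marking), connected
    component clone calling with founder-event accounting, merger-versus-expansion
    inference, vessel clonality classification, and a single-cell pipeline
    (QC filtering, PCA and graph clustering, haematopoietic contaminant removal,
    marker detection, group composition testing, and gene-signature module
    scoring for endothelial-to-mesenchymal transition).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    FNN,
    irlba,
    Rtsne,
    yaml,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
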