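Package: plasmamir
Title: Plasma Circulating microRNA Biomarker Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for plasma circulating microRNA
    (miR) biomarker studies that combine a pooled-sample microarray discovery
    phase with an RT-qPCR validation phase. Implements microarray present-calls,
    background subtraction and global median normalization; per-sample RT-qPCR
    quality control (reference-miR expression cutoff and a median-normalized
    miR-451 haemolysis score) and assay amplification-efficiency checks from
    dilution series; geNorm reference-stability M-values and a group-aware
    variance-share score; median-of-panel delta-Cq normalization with linear
    fold changes; Mann-Whitney differential testing with Benjamini-Hochberg
    false discovery rate control, Spearman correlations and exact categorical
    tests; and unsupervised Ward/Euclidean hierarchical clustering with Newick
    export. A seeded synthetic-cohort generator emulates the data structure of
    such studies (pooled discovery groups, injected group fold changes, stable
    reference miRs, haemolysis-contaminated and low-yield samples) so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
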