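Package: symbiotrx
Title: Dual-Organism Metatranscriptome Analysis of Ectomycorrhizal Symbiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of mixed host-symbiont (pine root +
    ectomycorrhizal fungus) RNA-seq: tiered read partitioning against
    rRNA/16S/fungal/plant reference panels, desk-scale de novo assembly and
    translated-similarity classification of unassigned reads, median-of-ratios
    normalization with Welch t-test / fold-change / Benjamini-Hochberg
    differential-expression gating, cross-species derivation of common and
    pair-unique upregulated gene sets, and small-secreted-protein (SSP)
    effector classification. Includes a truth-labelled synthetic data
    generator emulating the statistical structure of a compatible versus
    incompatible Suillus-Pinus inoculation experiment, so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
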