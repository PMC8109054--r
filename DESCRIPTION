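Package: vivoscreen
Title: Analysis and Simulation of In Vivo Pooled CRISPR Knockout Screens
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled CRISPR-Cas9 dropout/enrichment screens run in
    transplanted animals, where an engraftment bottleneck dominates the noise.
    Models the sgRNA library, assigns sequencing reads to guides by anchored
    spacer matching, normalizes counts to reads per million, scores guides by
    the median across-replicate T12/T0 fold change, ranks genes by the number
    of guides past a fold-change threshold, and quantifies CRISPR editing from
    amplicon reads via global alignment and an indel-at-cut-site window rule.
    Includes a generative simulator (skewed plasmid pool, transduction,
    per-animal engraftment bottleneck, selection, overdispersed sequencing)
    that emits ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
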