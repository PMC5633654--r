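Package: methmap
Title: Segmentation and Comparative Analysis of DNA Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis: segmentation of per-CpG methylation calls into hypomethylated
    regions (HMRs) with a two-state beta-binomial hidden Markov model,
    construction of a common/frequent/tissue-specific HMR catalog across
    normal tissues, differentially methylated region (DMR) calling from
    confidence bands on locally smoothed methylation profiles, cohort-scale
    promoter hypermethylation event detection and positive-selection
    candidate filtering on array-style beta matrices, and a burden-weighted
    permutation test for mutually exclusive hypermethylation across gene
    sets. A seed-deterministic synthetic-methylome generator with planted
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    IRanges,
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
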