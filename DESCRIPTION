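Package: plasmaTrace
Title: Copy Number Profiling, Somatic Variant Filtering and Clonal
    Evolution from Plasma Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for liquid-biopsy (cell-free DNA) genomics:
    fragment-size quality control of plasma DNA, read-count binning and
    circular binary segmentation of sparse whole-genome sequencing data
    with MergeLevels post-processing, copy-number-alteration calling and
    aneuploidy classification, a post-caller somatic variant filter
    cascade, purity- and copy-number-normalized cellular prevalence with
    longitudinal mutation clustering and clone-tree inference, and the
    accompanying clinical statistics (rank-sum tests, Kaplan-Meier /
    log-rank survival, Cox proportional hazards, Benjamini-Hochberg
    adjustment). Includes a synthetic-cohort simulator that generates
    clone trees with copy-number and mutation payloads, purity-diluted
    bin counts and allele frequencies over serial timepoints, bimodal
    fragment-size mixtures with nucleosome harmonics, and
    ploidy-correlated survival data, so the whole pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    survival,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
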