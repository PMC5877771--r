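Package: coremir
Title: Core Gene and Master-Regulator miRNA Nomination by Multi-Omic
    Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative analysis pipeline for count-based tumor
    profiling studies that nominates "core genes" -- genes that are
    simultaneously differentially expressed, copy-number altered in the
    concordant direction, and consensus targets of oppositely deregulated
    miRNAs -- and then nominates a master-regulator miRNA whose targets
    are over-represented in a gene co-expression network.  Includes an
    exact negative-binomial two-group test with common-dispersion
    estimation by conditional maximum likelihood, a simplified
    GISTIC-style gene-level copy-number caller with permutation q-values,
    multi-database miRNA-target consensus voting, Fisher-exact network
    enrichment, cross-validated random-forest AUC evaluation of candidate
    signatures, and a synthetic multi-omic cohort generator with planted,
    direction-consistent signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    randomForest,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
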