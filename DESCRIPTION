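Package: panelforge
Title: Design and Evaluation of High-Density SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for designing fixed-content SNP genotyping arrays and
    evaluating them after genotyping. Implements a candidate-elimination
    cascade for Infinium-style assays (assay-incompatible allele pairs,
    ambiguous or non-unique flanking sequence, clustered variants, paralog
    signals), empirical priority scoring from Sanger validation outcomes and
    a selection index combining priority with the vendor design score,
    euchromatin/heterochromatin partitioning of chromosomes from Marey maps
    (cumulative genetic vs. physical distance), proportional per-region quota
    allocation with an iterative smallest-gap thinning algorithm for even
    marker spacing, and post-genotyping evaluation: call-rate association
    with scores, minor-allele-frequency profiles, pairwise genetic distances,
    per-locus and windowed Weir-Cockerham F_st with permutation significance
    and selection-signature region flagging. A synthetic-data module
    generates reference genomes, candidate catalogs, linkage maps,
    validation outcomes and multi-population genotype matrices so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
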