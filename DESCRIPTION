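Package: mirpipe
Title: Small RNA-Seq miRNA Discovery and Profiling for Two-Library Designs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for
    two-library (e.g. fetal versus adult tissue) designs: adapter trimming
    and read cleaning with a conservation-checked filter ledger, perfect-match
    genome mapping of unique tags, priority-based annotation of tags into RNA
    categories, conserved miRNA profiling (arm usage, families, per-position
    nucleotide bias, single-base edits, 5'/3' end variants), novel miRNA
    discovery by hairpin folding with minimal-free-energy-index screening
    criteria, exact count-based differential expression between libraries,
    and stem-loop qPCR relative quantification by the 2^-ddCt method. A
    fully specified synthetic-data generator with planted ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, GeneExpression, DifferentialExpression
RoxygenNote: 7.3.3
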