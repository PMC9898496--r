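Package: pgcepi
Title: Promoter Chromatin States, Demethylation Escapees and X-Dosage
    Analysis for Germline Epigenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis toolkit for histone-modification profiling
    of developing germ cells. Classifies promoters into four chromatin
    states (H3K4me3-only, H3K27me3-only, bivalent, unmarked) from called
    peak sets and tracks their dynamics across developmental stages;
    computes observed/expected genomic enrichment of peak sets; calls DNA
    demethylation escapees in non-overlapping 5-kb bins, at promoters and
    for transposable-element subfamilies in a globally hypomethylated
    background; scores transposable-element copies by their
    H3K4me3:H3K9me3 balance; and estimates the X-to-autosome expression
    dosage factor between sexes. Includes a fully seeded synthetic
    epigenome generator with planted ground truth so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    IRanges,
    GenomicRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
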