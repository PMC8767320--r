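Package: mxpipe
Title: Assembly Statistics, Annotation Transfer and Motif Analysis for a
    Long-Read Protist Genome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis layer for a long-read (nanopore) genome project on the
    amitochondriate flagellate Monocercomonoides exilis: assembly-structure
    statistics (N50, GC, telomeric-end classification, chromosome-number
    estimation, coding-density windows), clustering-verified annotation
    transfer between assembly versions with fusion/split bookkeeping and
    locus-tag naming, 3'UTR polyadenylation-signal and Kozak-context motif
    analysis, and a composite screen for mitochondrial hallmark proteins
    (reciprocal best hits, dual targeting-signal consensus, tail-anchor and
    beta-signal/MBOMP filters). A seeded synthetic-data generator with
    ground-truth manifests makes every stage testable without external data
    or external bioinformatics binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
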