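Package: trnaproc
Title: Small-RNA Profiling of Endosymbiont tRNA Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for small-RNA sequencing of reduced-genome
    bacterial endosymbionts. Places 18-100 nt reads on annotated genomes with
    a mismatch-tolerant Hamming mapper, classifies per-read tRNA maturation
    states (5' leaders, 3' trailers, stepwise C/CC/CCA addition) and
    anticodon-loop halves, calls candidate base-modification sites from
    pileup mismatch fractions, compares libraries by relative tRNA abundance,
    discovers unannotated tRNA-like transcripts and chimeric ligation
    artifacts from collapsed reads, and scores codon decodability, four-box
    tRNA redundancy and aminoacyl-tRNA synthetase completeness. Includes a
    seeded synthetic-read simulator with per-read ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
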