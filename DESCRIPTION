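Package: trnaproc
Title: Organellar tRNA End-Processing Analysis from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies 5'-leader and 3'-trailer processing of plastid and
    mitochondrial tRNAs from aligned small-RNA sequencing reads. Reads are
    assigned to mature tRNA regions and +/-50 bp flanks by minimum-overlap
    fractions, a processing efficiency rate (PER, the log2 ratio of mature to
    flank read counts) is computed per tRNA and sample, and differential
    processing between two samples is tested with Fisher's exact test and
    Benjamini-Hochberg correction. Also provides RPKM/MA accumulation
    analysis, priority-ordered read annotation statistics, a chromatogram
    peak-height editing-efficiency statistic, and a synthetic organellar
    genome and read simulator with analytic expectations for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
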