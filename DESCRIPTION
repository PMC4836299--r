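Package: orthocombine
Title: Orthogonal Dual-Platform Confirmation of Exome Variant Calls
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes small-variant calls from two independent exome
    sequencing platforms (hybrid-capture/reversible-terminator and
    amplicon/semiconductor roles), normalizes and decomposes variant
    representations so equivalent calls compare equal, classifies every
    call by cross-platform concordance and coverage into confidence
    categories (Orthogonally Confirmed, Reliable, Likely True Positive,
    Likely False Positive), benchmarks call sets against a truth set
    (sensitivity, false positives per megabase, positive predictive
    value, per category and overall), cross-tabulates categories between
    replicate runs, and analyzes per-exon coverage complementarity and
    GC bias between platforms. Includes a synthetic-fixture generator
    that emulates truth sets, platform call sets with configurable error
    structure, and GC-biased coverage tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: VariantDetection, Sequencing, Coverage, QualityControl
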