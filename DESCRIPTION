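Package: tilesplice
Title: Detection of Condition-Regulated Alternative Splicing from
    Genome Tiling Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects condition-regulated alternative splicing, in
    particular intron retention, from whole-genome tiling microarray
    data. Maps 25-mer probes onto annotated gene models (one base
    transcript per gene, segmented into exons and introns), performs
    RMA-style preprocessing (normal+exponential background correction,
    quantile normalization, log2 transformation), calls differentially
    expressed genes by t-test with Benjamini-Hochberg correction and a
    fold-change filter, and tests each intron for differential signal
    by combining probe-level one-sided t-tests with Fisher's method in
    both directions. Significant introns are classified as retained or
    unknown splice type. Includes overlap statistics (representation
    factor and hypergeometric enrichment) for comparing event lists,
    vector-based correlation of fold-change profiles against stress
    indexes, and a synthetic-data generator that produces complete fake
    experiments with planted splicing events for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.3)
Imports:
    GenomicRanges,
    graphics,
    IRanges,
    S4Vectors,
    limma,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
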