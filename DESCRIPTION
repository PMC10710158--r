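Package: cnvrpop
Title: Copy Number Variation Region Construction and Population
    Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds copy number variation regions (CNVRs) from per-sample
    read-depth CNV calls by length and placement filtering, within-population
    recurrence filtering, and single-linkage merging under a reciprocal
    overlap criterion; classifies regions as duplication, deletion or mixed;
    computes the Vst population-differentiation statistic on per-region copy
    numbers with empirical top-percentile selection of differentiated
    regions; annotates regions positionally against gene models, QTL tables
    and published CNVR sets; and simulates multi-population CNV cohorts with
    known per-locus copy-number distributions and analytic expected Vst for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
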