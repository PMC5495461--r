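Package: sirnaflow
Title: Endogenous siRNA Duplex Calling, Exact Tag-Count Statistics, and
    Target Association for Staged Small-RNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls endogenous small interfering RNA (siRNA) duplexes from
    perfectly mapped small-RNA tags using the canonical two-nucleotide
    3' overhang geometry, tests per-tag differential expression between
    single pooled libraries with an exact tag-count statistic, links
    differentially expressed siRNAs to target genes through cleavage-site
    complementarity and through 24-nt-siRNA-directed DNA methylation,
    and summarizes target genes by expression-pattern clustering and
    functional-term over-representation. A synthetic-data generator with
    planted, recorded ground truth makes every stage testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
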