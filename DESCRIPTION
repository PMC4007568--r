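Package: clipsv
Title: Split-Read Structural Variant Detection and Heterogeneity
    Estimation from Soft-Clipped Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural variants (deletions, tandem duplications,
    inversions) at base-pair resolution from clusters of soft-clipped reads
    in a coordinate-sorted alignment, iteratively refines soft-clipping near
    candidate breakpoints by targeted Smith-Waterman local realignment,
    estimates the heterogeneity percentage of each variant from spanning
    versus soft-clipped read counts at its breakpoints, and applies a chosen
    set of variants to the reference to emit a personal genomic sequence.
    Includes a paired-end read simulator for heterogeneous two-haplotype
    samples so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
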