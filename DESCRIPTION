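Package: pairsynt
Title: Head-to-Head Gene-Pair Microsynteny and Collagen IV Chain Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for head-to-head (divergently
    transcribed) gene pairs, built around the collagen IV gene family.
    Detects divergent gene pairs in genome annotations, anchors cross-species
    gene naming by reciprocal-best-hit protein alignment against a reference
    proteome, compares flanking-gene microsynteny windows to call
    conservation, inversion, rearrangement and precise-deletion events,
    assigns duplicated chains to alpha1-type or alpha2-type progenitors from
    NC1-domain distance trees, annotates collagen Gly-X-Y domain architecture,
    and tests per-pair cysteine content for association with habitat salinity
    by seeded permutation. Ships a synthetic-clade simulator that plants
    pair duplications, inversions, precise deletions and lineage-specific
    cysteine gains with machine-readable truth tables, so every pipeline
    stage is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
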