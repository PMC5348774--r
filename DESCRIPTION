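Package: guidekit
Title: Exhaustive SpCas9 Guide RNA Design and Scoring for Coding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Enumerates every SpCas9 (NGG) guide RNA targeting the
    protein-coding regions of a gene and scores each guide with a
    ten-parameter panel: position within the master coding DNA sequence
    (percent peptide), transcript representation, Rule Set 1 on-target
    activity, aggregate off-target specificity (Hsu 2013 style,
    NGG and NAG PAMs), GC content, homopolymer and uracil-triplet flags,
    and a microhomology-based out-of-frame score. Includes threshold
    filtering, deterministic CSV export, and a synthetic mini-genome
    generator with truth-tracked planted features for fully offline
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
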