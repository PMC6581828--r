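Package: tadacall
Title: Targeted DamID Occupancy Tracks, Peak Calling and Transcription-State Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Targeted DamID (TaDa) experiments from per-GATC-fragment
    Dam and Dam-fusion read counts to gene-level target calls. Provides
    library-size normalized log2(Dam-fusion/Dam) ratio tracks, replicate
    quality control, permutation-based false discovery rates for binding peaks
    formed of consecutive GATC fragments, consensus peaks across replicates,
    distance-based target-gene assignment with an intervening-gene rule,
    RNA polymerase II occupancy transcription-state calling with a fitted FDR
    surface over enrichment and gene size, gene-set integration utilities, and
    a synthetic-data generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
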