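Package: strexpand
Title: Genome-Wide Detection of Rare Short Tandem Repeat Expansions from
    Short-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects rare short tandem repeat (STR) expansions genome-wide
    from paired-end short-read sequencing data. Builds an STR-decoy-augmented
    reference genome from the set of canonical 1-6 bp repeat motifs, allocates
    reads mapping to the decoy chromosomes back to genomic STR loci using
    their mate-pair positions, flags unusually repeat-rich loci with a robust
    z-score based on Huber's M-estimator of location and scale with
    Benjamini-Hochberg multiple-testing correction, and estimates expanded
    allele sizes by inverting a simulation-calibrated log-log regression of
    normalized decoy coverage on allele size. Includes a deterministic
    paired-end read simulator that emits decoy-aware SAM streams with truth
    tables, used for calibration and for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
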