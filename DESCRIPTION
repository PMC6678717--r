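Package: splicescope
Title: Long-Read Transcriptome Toolkit: Splicing Events, TSS Proximity
    Filtering and lncRNA Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for downstream analysis of transcript models derived from
    long-read (third-generation) RNA sequencing. Validates full-length
    transcripts by the distance of their start sites to regulatory feature
    tracks (CAGE peaks, histone marks), classifies the seven local
    alternative-splicing event types (SE, A5, A3, MX, RI, AF, AL) from
    transcript structure, compares per-sample splicing profiles with a
    chi-squared homogeneity test, scores per-gene isoform diversity as
    Shannon entropy of isoform usage, combines coding-potential calls from
    two external classifiers, matches candidate transcripts against a
    lncRNA reference catalog by intron-chain identity, extracts
    tissue-specific novel lncRNAs, and performs hypergeometric GO
    over-representation analysis. Includes a seeded synthetic-data
    generator producing every input format with known ground truth, and
    plotting functions that emit machine-readable layout manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
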