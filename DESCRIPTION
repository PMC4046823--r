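Package: peakfusion
Title: Consensus Fusion of ChIP-Seq Peak Calls and Detection of
    Post-Translationally Modified Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-peak-calling analysis for ChIP-seq experiments that target a
    post-translational modification (such as SUMO-1) rather than a single
    transcription factor. Peak sets from two or more peak callers are combined
    by coverage-level union or intersection; fused peaks are annotated with
    transcription factor binding sites (TFBS) and promoter windows around
    transcription start sites; each transcription factor receives a
    TFBS-weighted peak-height score; candidate modified factors are flagged
    with the Hampel identifier (median/MAD outlier rule); and competing
    callers or fusion strategies are compared with four promoter/TFBS
    precision indices and their average. Includes a seeded synthetic-data
    generator with a planted high-signal factor, readers for BED, ENCODE
    narrowPeak, MACS tables, UCSC tfbsConsSites dumps and TSS tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
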