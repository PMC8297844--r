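Package: milkit
Title: Discovery of Fungal microRNA-Like RNAs and Cross-Kingdom Target
    Prediction from Small RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end small-RNA-sequencing workflow for fungi that
    interact with plant hosts: quality- and adapter-based read cleansing
    with full accounting, collapsing of reads to unique sequence tags,
    genome mapping and non-coding-RNA classification, identification of
    known microRNA-like RNAs (milRNAs) against a mature miRNA reference,
    de novo milRNA calling from hairpin precursors under eleven
    structural criteria evaluated with a thermodynamic folding engine
    (ViennaRNA), TPM expression normalisation, duplex-based target-site
    scoring with G:U wobble penalties, a six-rule fungal self-target
    verification, a cross-kingdom ("transboundary") eligibility screen
    based on host-genome matches and flank-fold stability, and a
    three-ruleset consensus for host target prediction. Includes a
    synthetic-data generator that plants hairpins, contamination classes
    and target sites with known ground truth so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    withr
SystemRequirements: ViennaRNA (RNAfold, RNAduplex on PATH)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
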