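Package: adarkit
Title: Design of ADAR-Recruiting Guide RNAs and Quantification of A-to-I RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for programmable adenosine-to-inosine (A-to-I) RNA editing
    studies that recruit endogenous ADAR with antisense guide RNAs (arRNAs).
    Designs guides against a target adenosine (pairing-arm nomenclature,
    cytidine mismatch opposite the target, uracil deletions opposite bystander
    adenosines, poly(AC) linkers) and assembles them into ribozyme-flanked
    circularization cassettes; quantifies per-site editing from targeted
    amplicon reads and calls genuine edits against an empirical noise
    threshold; calls differentially edited and candidate sequence-dependent
    off-target sites from replicate count tables with Fisher's exact test and
    Benjamini-Hochberg correction; computes a simplified Alu Editing Index;
    and provides RNAscope H-score and qPCR standard-curve quantification.
    Includes simulators for every input so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
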