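Package: mirarm
Title: Arm-Resolved microRNA Profiling and Target Prediction from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully deterministic pipeline for arm-resolved
    microRNA analysis of small RNA sequencing libraries across developmental
    stages. Reads are adapter-trimmed, length-filtered (19-24 nt) and mapped
    to hairpin precursor sequences; mature 5p/3p miRNAs (including novel
    arms) are called from read-start peaks, verified against the hairpin
    stem with an internal base-pair-maximisation folder, and quantified into
    a stage-by-mature expression table with RPM normalisation. Downstream
    analytics cover arm dominance and arm-switching detection, Shannon
    entropy expression diversity, and hierarchical clustering of stages.
    miRNA regulatory elements (MREs) in 3'UTRs are predicted with a
    nearest-neighbor duplex free-energy model (Watson-Crick and G:U wobble
    stacking at 37 C), seed-class annotation (canonical, G:U seed,
    3'-compensatory, seedless), empirical dinucleotide-shuffle p-values, and
    cross-species conservation filtering into a miRNA-target network. A
    synthetic-data module simulates hairpins, stage-wise read libraries with
    planted arm switching, and UTRs with planted MREs, each with truth
    tables, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
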