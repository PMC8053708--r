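Package: cpaseq
Title: Terminus- and Methylation-Aware Small RNA Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of small RNA sequencing libraries in
    which molecules carry heterogeneous 5'/3' terminus chemistries
    (5'-P/OH/m7G-cap/m3G-cap/ppp; 3'-OH/P/cyclic-P/aminoacyl) and
    methylated nucleosides (m1A, m3C, m1G). Implements a generative model
    of combinatorial enzymatic end-repair (deacylation, Cap-Clip, T4 PNK,
    AlkB) with TGIRT reverse transcription, adapter/UMI library synthesis,
    and the matching analysis pipeline: adapter trimming and UMI
    deduplication, an ordered annotation cascade over small RNA reference
    classes with tRNA-fragment typing, RPM and miRNA-anchored
    normalization, treatment-responsive species calling, a
    misincorporation-based methylome caller with stoichiometry estimates,
    and multi-tissue expression statistics (tissue specificity index,
    enrichment filters, per-class clustering, differential species).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
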