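Package: oligolock
Title: Design and Evaluation of Blocking Oligonucleotides for Globin mRNA Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for designing 3'-blocked oligonucleotides that mask the
    oligo-dT priming site of abundant poly-adenylated transcripts (globin
    mRNAs by default) before reverse transcription, and for evaluating the
    depletion outcome. Covers nearest-neighbor duplex thermodynamics with
    monovalent-salt and oligo-concentration corrections, maximum-base-pairing
    prediction of 3'-end accessibility, linear and circular blocker
    architectures with poly-T tails and validation rules, k-mer seed-and-extend
    off-target screening against a transcriptome and spike-in registry, and
    depletion statistics from RNA-seq count tables and qPCR Ct tables
    (class prevalence, reduction fold change, spike-in correlation, detection
    sets, Wilson confidence intervals, dilution-limited relative
    quantification). Seeded generators produce all synthetic fixtures:
    globin-like transcripts with engineered 3'-end structure, orthogonal
    spike-in sets, count matrices and Ct tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
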