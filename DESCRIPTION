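Package: prxia
Title: Dropout-Aware Interactome Analysis for Peroxiredoxin Pull-Downs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for disulfide-dependent peroxiredoxin
    interactomes measured by immunoprecipitation mass spectrometry with
    label-free quantification (LFQ). Implements missing-value-aware
    differential abundance via a probabilistic dropout likelihood that
    uses both observed intensities and the informative absence of missing
    ones, permutation-calibrated log2 fold-change thresholds, multi-contrast
    classification of interactors (cysteine-dependent, isoform-specific,
    and the sulfenic-acid versus disulfide-relay mechanism split),
    redox-sensitivity and subcellular-compartment enrichment, and
    cysteine-centered sequence analyses (global alignment similarity,
    flanking amino-acid composition, and iterative motif discovery).
    Includes a planted-truth synthetic data generator so the whole
    pipeline is testable end to end without external downloads.
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
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
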