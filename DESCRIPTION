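Package: somaticsieve
Title: Tissue-Specific Somatic SNV Screening from Paired Ultra-Deep
    Targeted Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rare tissue-specific somatic single-nucleotide variants
    from paired affected/reference (e.g. brain/blood) ultra-deep targeted
    sequencing. Harmonizes call sets from multiple somatic callers (MuTect,
    MuTect2, Strelka2, VarScan2), applies a paired-count somatic filter
    (depth, alternative allele depth, allele-frequency bounds, brain/blood
    frequency ratio, exact test on read counts, cohort recurrence), and
    classifies candidate sites by cross-caller consensus. Includes
    rare-event droplet digital PCR quantification (merged-well Poisson
    concentration, fractional abundance with confidence intervals,
    acceptance QC) and a synthetic paired-cohort generator with known
    ground truth for end-to-end validation of the screen.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
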