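#' Bundled candidate-site count table
#'
#' Per-caller brain/blood read counts for eleven validated candidate
#' tissue-specific SNVs from a published ultra-deep (~700x) paired
#' brain/blood targeted-sequencing study of Alzheimer patients, as printed
#' in the study's candidate table (MuTect1 reported only one of the
#' sites). Useful as a worked example for [evaluate_criteria()] and
#' [consensus_classify()]: with default thresholds every listed count pair
#' passes the per-pair criteria, and the chr1:207461994C>T site is
#' supported by all four callers.
#'
#' @return A tibble with columns `group`, `individual`, `chrom`, `pos`,
#'   `ref`, `alt`, `location`, `caller`, `blood_ref`, `blood_alt`,
#'   `brain_ref`, `brain_alt`, `comments`.
#' @export
brain_snv_candidates <- function() {
  path <- system.file("extdata", "brain_snv_candidates.tsv",
                      package = "somaticsieve", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    blood_ref = readr::col_integer(),
                    blood_alt = readr::col_integer(),
                    brain_ref = readr::col_integer(),
                    brain_alt = readr::col_integer(),
                    .default = readr::col_character()))
}

#' Bundled synthetic ddPCR well table
#'
#' A small synthetic two-sample rare-event ddPCR well table (constructed,
#' not measured) whose merged counts yield a mutant fractional abundance
#' of ~0.39% in the brain sample and ~0 in blood, matching the scale of a
#' validated rare somatic variant. Useful as a worked example for
#' [ddpcr_quantify()].
#'
#' @return A tibble of wells (see [read_ddpcr_wells()]).
#' @export
ddpcr_wells_synthetic <- function() {
  read_ddpcr_wells(system.file("extdata", "ddpcr_wells_synthetic.csv",
                               package = "somaticsieve", mustWork = TRUE))
}
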