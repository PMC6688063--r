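#' Read a paired tumor/normal VCF into a site-call table
#'
#' Reads a VCF 4.x file produced by one of the supported somatic callers in
#' paired mode (affected tissue as "tumor", reference tissue as "normal";
#' here brain vs blood) and extracts per-tissue reference/alternative read
#' counts for every biallelic SNV record. Each caller encodes read counts in
#' its own FORMAT fields, so the `dialect` argument selects the extraction
#' rule:
#'
#' * `mutect1`, `mutect2`, `synthetic`: per-sample allelic depth `AD`
#'   ("ref,alt");
#' * `varscan2`: separate reference depth `RD` and alternative depth `AD`
#'   fields;
#' * `strelka2`: tier-1 per-base count fields (`AU`, `CU`, `GU`, `TU`),
#'   taking the tier-1 count of the REF and ALT bases.
#'
#' Multiallelic and indel records are skipped (their number is recorded in
#' the `provenance` attribute). FILTER values are retained verbatim in the
#' `comments` column; nothing is rejected at this stage -- default caller
#' filters discard most genuine low-frequency somatic variants, so all
#' downstream rejection is left to the explicit somatic filter.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param dialect Caller that produced the file; one of `"mutect1"`,
#'   `"mutect2"`, `"strelka2"`, `"varscan2"`, `"synthetic"`.
#' @param individual Identifier for the individual (sample pair).
#' @param tumor_sample,normal_sample Names of the tumor (brain) and normal
#'   (blood) sample columns. When `NULL`, columns named (case-insensitively)
#'   `TUMOR`/`BRAIN` and `NORMAL`/`BLOOD` are used.
#' @return A tibble with one row per retained SNV: `individual`, `caller`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `brain_ref`, `brain_alt`,
#'   `blood_ref`, `blood_alt`, `comments`. A `provenance` attribute records
#'   the source path, dialect and skipped-record counts.
#' @examples
#' \dontrun{
#' calls <- read_vcf_calls("pair01_mutect2.vcf", "mutect2", "pair01")
#' }
#' @export
read_vcf_calls <- function(path, dialect, individual,
                           tumor_sample = NULL, normal_sample = NULL) {
  dialect <- tolower(dialect)
  if (!dialect %in% CALLER_DIALECTS) {
    abort(sprintf("unknown caller dialect '%s'; supported: %s",
                  dialect, paste(CALLER_DIALECTS, collapse = ", ")))
  }
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  empty <- tibble::tibble(
    individual = character(), caller = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), brain_ref = integer(), brain_alt = integer(),
    blood_ref = integer(), blood_alt = integer(), comments = character()
  )
  if (n_rec == 0) {
    return(with_provenance(empty, path, dialect, 0L, 0L))
  }

  samples <- colnames(vcf@gt)[-1]
  tumor <- resolve_sample(samples, tumor_sample, c("tumor", "brain"), path)
  normal <- resolve_sample(samples, normal_sample, c("normal", "blood"), path)

  ref <- fix$REF
  alt <- fix$ALT
  is_snv <- !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  n_multi <- sum(!is.na(alt) & grepl(",", alt, fixed = TRUE))
  n_skipped <- sum(!is_snv)

  keep <- which(is_snv)
  if (length(keep) == 0) {
    return(with_provenance(empty, path, dialect, n_skipped, n_multi))
  }

  brain <- extract_counts(vcf, keep, tumor, dialect, ref, alt)
  blood <- extract_counts(vcf, keep, normal, dialect, ref, alt)

  out <- tibble::tibble(
    individual = individual,
    caller = dialect,
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = ref[keep],
    alt = alt[keep],
    brain_ref = brain$ref,
    brain_alt = brain$alt,
    blood_ref = blood$ref,
    blood_alt = blood$alt,
    comments = ifelse(is.na(fix$FILTER[keep]), "", fix$FILTER[keep])
  )
  out <- dplyr::distinct(out, dplyr::across(dplyr::all_of(CALL_KEY_COLS)),
                         .keep_all = TRUE)
  with_provenance(out, path, dialect, n_skipped, n_multi)
}

with_provenance <- function(calls, path, dialect, n_skipped, n_multiallelic) {
  attr(calls, "provenance") <- list(
    source = path, dialect = dialect,
    n_skipped_non_snv = as.integer(n_skipped),
    n_multiallelic = as.integer(n_multiallelic)
  )
  calls
}

resolve_sample <- function(samples, requested, conventions, path) {
  if (!is.null(requested)) {
    if (!requested %in% samples) {
      abort(sprintf("sample column '%s' not found in %s (samples: %s)",
                    requested, path, paste(samples, collapse = ", ")))
    }
    return(requested)
  }
  hit <- samples[tolower(samples) %in% conventions]
  if (length(hit) != 1) {
    abort(sprintf(
      "cannot identify the %s sample column in %s (samples: %s); pass tumor_sample/normal_sample explicitly",
      conventions[1], path, paste(samples, collapse = ", ")))
  }
  hit
}

# Per-dialect ref/alt read-count extraction for the rows in `keep`.
extract_counts <- function(vcf, keep, sample, dialect, ref, alt) {
  gt_field <- function(element) {
    m <- vcfR::extract.gt(vcf, element = element, as.numeric = FALSE)
    m[keep, sample]
  }
  int1 <- function(x, i = 1) {
    parts <- stringr::str_split(x, ",")
    as.integer(vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_,
                      character(1)))
  }
  if (dialect %in% c("mutect1", "mutect2", "synthetic")) {
    ad <- gt_field("AD")
    list(ref = int1(ad, 1), alt = int1(ad, 2))
  } else if (dialect == "varscan2") {
    list(ref = as.integer(gt_field("RD")), alt = as.integer(gt_field("AD")))
  } else { # strelka2: tier-1 counts of the ref and alt bases
    base_counts <- lapply(c(A = "AU", C = "CU", G = "GU", T = "TU"),
                          function(f) int1(gt_field(f), 1))
    pick <- function(bases) {
      vapply(seq_along(keep),
             function(i) base_counts[[bases[keep[i]]]][i], integer(1))
    }
    list(ref = pick(ref), alt = pick(alt))
  }
}

#' Comment strings that disqualify MuTect calls
#'
#' The five MuTect/MuTect2 judgement annotations treated as evidence of an
#' alignment or calling artifact. Calls carrying any of these comments are
#' dropped before the somatic filter; all other caller FILTER values
#' (e.g. `t_lod_fstar`, `LowEVS`) are recorded but never cause rejection.
#'
#' @return Character vector of disqualifying comment patterns.
#' @export
mutect_exclusion_patterns <- function() {
  c("clustered events", "poor mapping region", "nearby gap",
    "triallelic sites", "strand artifact")
}

# Case-insensitive substring match with spaces and underscores equivalent.
normalise_comment <- function(x) {
  stringr::str_squish(stringr::str_replace_all(tolower(x), "[_ ]+", " "))
}

#' Drop calls carrying disqualifying caller comments
#'
#' Removes site calls whose `comments` match any of the given patterns
#' (case-insensitive substring, with spaces and underscores treated as
#' equivalent), but only for calls from the callers in `applies_to`. By
#' default only the MuTect callers' five artifact annotations disqualify a
#' call; other callers pass through untouched.
#'
#' @param calls A site-call tibble (see [read_vcf_calls()]).
#' @param patterns Character vector of disqualifying comment patterns.
#' @param applies_to Callers whose comments are acted upon.
#' @return `calls` without the disqualified rows; the number of removals is
#'   recorded in the `n_comment_excluded` attribute.
#' @export
exclude_commented_calls <- function(calls,
                                    patterns = mutect_exclusion_patterns(),
                                    applies_to = c("mutect1", "mutect2")) {
  assert_site_calls(calls)
  if (length(patterns) == 0) abort("`patterns` must be non-empty")
  if (nrow(calls) == 0 || !"comments" %in% names(calls)) {
    attr(calls, "n_comment_excluded") <- 0L
    return(calls)
  }
  pat <- normalise_comment(patterns)
  norm <- normalise_comment(calls$comments)
  hit <- Reduce(`|`, lapply(pat, function(p) stringr::str_detect(norm, stringr::fixed(p))))
  hit[is.na(hit)] <- FALSE
  drop <- hit & calls$caller %in% applies_to
  out <- calls[!drop, , drop = FALSE]
  attr(out, "n_comment_excluded") <- sum(drop)
  out
}

#' Write a candidate table
#'
#' Writes consensus screening results as a tab-separated candidate table,
#' one row per (site, individual, caller), mirroring the conventional
#' per-caller layout: locus, per-tissue ref/alt counts and allele
#' frequencies (percent, one decimal). The file round-trips through
#' [read_candidates_tsv()].
#'
#' @param results A `somatic_screen` object or its verdict-level tibble
#'   (as returned by `tidy(screen, "verdicts")`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(results, path) {
  if (inherits(results, "somatic_screen")) {
    verdicts <- dplyr::left_join(
      results$verdicts,
      dplyr::select(results$results, dplyr::all_of(
        c("individual", "chrom", "pos", "ref", "alt", "classification"))),
      by = c("individual", "chrom", "pos", "ref", "alt"))
  } else {
    verdicts <- results
  }
  cols <- c("individual", "caller", "chrom", "pos", "ref", "alt",
            "brain_ref", "brain_alt", "blood_ref", "blood_alt")
  assert_site_calls(verdicts, "results")
  out <- dplyr::as_tibble(verdicts[, intersect(
    c(cols, "classification", "passed"), names(verdicts)), drop = FALSE])
  out$locus <- locus_label(out$chrom, out$pos, out$ref, out$alt)
  out$brain_aaf_pct <- sprintf("%.1f", 100 * aaf(out$brain_ref, out$brain_alt))
  out$blood_aaf_pct <- sprintf("%.1f", 100 * aaf(out$blood_ref, out$blood_alt))
  out <- dplyr::arrange(out, .data$chrom, .data$pos, .data$individual,
                        .data$caller)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read back a candidate table written by [write_candidates_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with the same keys and counts that were written.
#' @export
read_candidates_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    brain_ref = readr::col_integer(),
                    brain_alt = readr::col_integer(),
                    blood_ref = readr::col_integer(),
                    blood_alt = readr::col_integer(),
                    brain_aaf_pct = readr::col_character(),
                    blood_aaf_pct = readr::col_character(),
                    .default = readr::col_guess()))
}
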