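#' Somatic filter thresholds
#'
#' Bundles the tunable thresholds of the paired somatic filter and the
#' consensus classifier. Defaults correspond to ultra-deep (~700x) targeted
#' screens for rare mosaic variants:
#'
#' * `min_depth` (50 reads): minimum total depth required in *both* tissues;
#' * `min_brain_alt` (5 reads): minimum alternative-allele depth in the
#'   affected tissue;
#' * `max_aaf` (0.20): both tissues must have alternative allele frequency
#'   strictly below this bound, which removes germline heterozygotes even
#'   under strong capture allelic imbalance;
#' * `ratio_low`, `ratio_high` (0.8, 1.2): calls whose brain/blood AAF ratio
#'   lies inside this closed window are excluded as shared signal;
#' * `alpha` (0.05): significance level for the exact test contrasting
#'   brain and blood allele counts;
#' * `fisher_sidedness`: `"two_sided_minlik"` (default; the minimum-
#'   likelihood two-sided convention) or `"one_sided_brain_enriched"`;
#' * `min_callers_possible` (3), `min_callers_specific` (4): caller-support
#'   thresholds for the `possible` and `tissue_specific` consensus classes;
#' * `recurrence_max_individuals` (1): a site passing the per-pair criteria
#'   in more than this many individuals is treated as a recurrent artifact
#'   and excluded everywhere.
#'
#' @param min_depth,min_brain_alt,max_aaf,ratio_low,ratio_high,alpha,fisher_sidedness,min_callers_possible,min_callers_specific,recurrence_max_individuals
#'   See above.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_depth = 50,
                              min_brain_alt = 5,
                              max_aaf = 0.20,
                              ratio_low = 0.8,
                              ratio_high = 1.2,
                              alpha = 0.05,
                              fisher_sidedness = c("two_sided_minlik",
                                                   "one_sided_brain_enriched"),
                              min_callers_possible = 3,
                              min_callers_specific = 4,
                              recurrence_max_individuals = 1) {
  fisher_sidedness <- match.arg(fisher_sidedness)
  stopifnot(min_depth >= 0, min_brain_alt >= 0,
            max_aaf > 0, max_aaf < 1,
            ratio_low < ratio_high,
            alpha > 0, alpha < 1,
            min_callers_possible >= 1,
            min_callers_possible <= min_callers_specific,
            min_callers_specific <= 4,
            recurrence_max_individuals >= 1)
  structure(list(
    min_depth = min_depth, min_brain_alt = min_brain_alt,
    max_aaf = max_aaf, ratio_low = ratio_low, ratio_high = ratio_high,
    alpha = alpha, fisher_sidedness = fisher_sidedness,
    min_callers_possible = as.integer(min_callers_possible),
    min_callers_specific = as.integer(min_callers_specific),
    recurrence_max_individuals = as.integer(recurrence_max_individuals)
  ), class = "filter_thresholds")
}

#' Alternative allele frequency
#'
#' `aaf(ref, alt)` is `alt / (ref + alt)`, the fraction of reads at a site
#' carrying the non-reference base. Vectorized.
#'
#' @param ref,alt Reference and alternative read counts (non-negative).
#' @return Fraction in `[0, 1]`.
#' @examples
#' aaf(582, 6)  # 0.0102..., printed as 1.0%
#' @export
aaf <- function(ref, alt) {
  if (any(ref < 0 | alt < 0, na.rm = TRUE)) abort("read counts must be >= 0")
  total <- ref + alt
  if (any(total == 0, na.rm = TRUE)) {
    abort("AAF is undefined at zero total depth")
  }
  alt / total
}

#' Brain/blood AAF ratio
#'
#' Returns `brain_aaf / blood_aaf` with the rare-variant conventions:
#' `Inf` when the blood AAF is 0 and the brain AAF is positive (absence in
#' blood is the strongest somatic evidence), and `NaN` when both are 0
#' (undefined; such a site fails the ratio criterion). Vectorized.
#'
#' @param brain_aaf,blood_aaf Allele frequencies in `[0, 1]`.
#' @return Extended-real ratio.
#' @export
aaf_ratio <- function(brain_aaf, blood_aaf) {
  if (any(brain_aaf < 0 | blood_aaf < 0, na.rm = TRUE)) {
    abort("allele frequencies must be >= 0")
  }
  ifelse(blood_aaf == 0,
         ifelse(brain_aaf == 0, NaN, Inf),
         brain_aaf / blood_aaf)
}

#' Exact test on paired allele counts
#'
#' Fisher's exact test on the 2x2 table
#' `[[brain_alt, brain_ref], [blood_alt, blood_ref]]`, asking whether the
#' alternative allele is differently represented in the two tissues.
#' `two_sided_minlik` is the minimum-likelihood two-sided convention (the
#' p-value sums the probabilities of all tables with the observed margins
#' whose point probability does not exceed the observed one);
#' `one_sided_brain_enriched` sums tables with at least the observed number
#' of alternative reads in brain. Vectorized over count vectors.
#'
#' @param brain_alt,brain_ref,blood_alt,blood_ref Read counts.
#' @param sidedness `"two_sided_minlik"` or `"one_sided_brain_enriched"`.
#' @return P-value(s) in `(0, 1]`.
#' @examples
#' fisher_exact(10, 997, 0, 1472)  # ~1.2e-4
#' @export
fisher_exact <- function(brain_alt, brain_ref, blood_alt, blood_ref,
                         sidedness = c("two_sided_minlik",
                                       "one_sided_brain_enriched")) {
  sidedness <- match.arg(sidedness)
  counts <- cbind(brain_alt, brain_ref, blood_alt, blood_ref)
  if (any(counts < 0)) abort("read counts must be >= 0")
  if (any(rowSums(counts) < 1)) abort("total count must be >= 1")
  alternative <- if (sidedness == "two_sided_minlik") "two.sided" else "greater"
  vapply(seq_len(nrow(counts)), function(i) {
    m <- matrix(counts[i, ], nrow = 2, byrow = TRUE)
    stats::fisher.test(m, alternative = alternative)$p.value
  }, numeric(1))
}

#' Evaluate the per-pair somatic filter criteria
#'
#' Applies the five per-pair criteria of the somatic filter to each site
#' call and records every outcome (criteria are always all evaluated, never
#' short-circuited, so the verdict table is fully populated):
#'
#' 1. `c1_depth`: total depth >= `min_depth` in both tissues;
#' 2. `c2_brain_alt`: brain alternative depth >= `min_brain_alt`;
#' 3. `c3_aaf`: AAF < `max_aaf` in both tissues (strict);
#' 4. `c4_ratio`: brain/blood AAF ratio outside the closed window
#'    `[ratio_low, ratio_high]` (an undefined ratio fails);
#' 5. `c5_fisher`: exact-test p-value < `alpha` (strict).
#'
#' The cohort-level recurrence criterion (`c6_recurrent`) is filled in by
#' [flag_recurrent()]; until then `passed` reflects criteria 1-5.
#'
#' @param calls A site-call tibble (see [read_vcf_calls()]).
#' @param thresholds A [filter_thresholds()] object.
#' @return `calls` with added columns `brain_depth`, `blood_depth`,
#'   `brain_aaf`, `blood_aaf`, `aaf_ratio`, `fisher_p`, `c1_depth` ...
#'   `c5_fisher`, `c6_recurrent` (`NA` until resolved) and `passed`.
#' @export
evaluate_criteria <- function(calls, thresholds = filter_thresholds()) {
  assert_site_calls(calls)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  out <- tibble::as_tibble(calls)
  if (nrow(out) == 0) {
    extra <- c("brain_depth", "blood_depth", "brain_aaf", "blood_aaf",
               "aaf_ratio", "fisher_p")
    for (col in extra) out[[col]] <- numeric(0)
    for (col in c("c1_depth", "c2_brain_alt", "c3_aaf", "c4_ratio",
                  "c5_fisher", "c6_recurrent", "passed")) {
      out[[col]] <- logical(0)
    }
    return(out)
  }
  out$brain_depth <- out$brain_ref + out$brain_alt
  out$blood_depth <- out$blood_ref + out$blood_alt
  if (any(out$brain_depth == 0 | out$blood_depth == 0)) {
    abort("site calls with zero depth in a tissue cannot be evaluated")
  }
  out$brain_aaf <- aaf(out$brain_ref, out$brain_alt)
  out$blood_aaf <- aaf(out$blood_ref, out$blood_alt)
  out$aaf_ratio <- aaf_ratio(out$brain_aaf, out$blood_aaf)

  # Exact tests are the expensive step: compute once per distinct table.
  tables <- dplyr::distinct(
    out[, c("brain_alt", "brain_ref", "blood_alt", "blood_ref")])
  tables$fisher_p <- fisher_exact(tables$brain_alt, tables$brain_ref,
                                  tables$blood_alt, tables$blood_ref,
                                  thresholds$fisher_sidedness)
  out <- dplyr::left_join(
    out, tables, by = c("brain_alt", "brain_ref", "blood_alt", "blood_ref"))

  out$c1_depth <- out$brain_depth >= thresholds$min_depth &
    out$blood_depth >= thresholds$min_depth
  out$c2_brain_alt <- out$brain_alt >= thresholds$min_brain_alt
  out$c3_aaf <- out$brain_aaf < thresholds$max_aaf &
    out$blood_aaf < thresholds$max_aaf
  in_window <- !is.nan(out$aaf_ratio) &
    out$aaf_ratio >= thresholds$ratio_low &
    out$aaf_ratio <= thresholds$ratio_high
  out$c4_ratio <- !in_window & !is.nan(out$aaf_ratio)
  out$c5_fisher <- out$fisher_p < thresholds$alpha
  out$c6_recurrent <- NA
  out$passed <- out$c1_depth & out$c2_brain_alt & out$c3_aaf &
    out$c4_ratio & out$c5_fisher
  out
}

#' Identify recurrent sites across a cohort
#'
#' A site whose call passes the per-pair criteria (1-5) in more than
#' `recurrence_max_individuals` distinct individuals is treated as a
#' recurrent systematic artifact.
#'
#' @param verdicts A verdict tibble from [evaluate_criteria()], pooled over
#'   the cohort (all individuals and callers).
#' @param thresholds A [filter_thresholds()] object.
#' @return Tibble of recurrent site keys (`chrom`, `pos`, `ref`, `alt`)
#'   with the number of affected individuals (`n_individuals`).
#' @export
find_recurrent <- function(verdicts, thresholds = filter_thresholds()) {
  key <- c("chrom", "pos", "ref", "alt")
  if (nrow(verdicts) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          n_individuals = integer()))
  }
  pass15 <- verdicts$c1_depth & verdicts$c2_brain_alt & verdicts$c3_aaf &
    verdicts$c4_ratio & verdicts$c5_fisher
  verdicts[pass15, , drop = FALSE] |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(key, "individual")))) |>
    dplyr::count(dplyr::across(dplyr::all_of(key)), name = "n_individuals") |>
    dplyr::filter(.data$n_individuals > thresholds$recurrence_max_individuals) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Resolve the recurrence criterion in a verdict table
#'
#' Fills `c6_recurrent` for every verdict (`FALSE` pass-state means the
#' site is recurrent and fails) and updates `passed` to the conjunction of
#' all six criteria.
#'
#' @inheritParams find_recurrent
#' @param recurrent Optional precomputed result of [find_recurrent()].
#' @return The verdict tibble with `c6_recurrent` resolved and `passed`
#'   final.
#' @export
flag_recurrent <- function(verdicts, thresholds = filter_thresholds(),
                           recurrent = NULL) {
  if (is.null(recurrent)) recurrent <- find_recurrent(verdicts, thresholds)
  if (nrow(verdicts) == 0) return(verdicts)
  key <- paste(verdicts$chrom, verdicts$pos, verdicts$ref, verdicts$alt)
  rec_key <- paste(recurrent$chrom, recurrent$pos, recurrent$ref, recurrent$alt)
  is_rec <- key %in% rec_key
  verdicts$c6_recurrent <- !is_rec
  verdicts$passed <- verdicts$c1_depth & verdicts$c2_brain_alt &
    verdicts$c3_aaf & verdicts$c4_ratio & verdicts$c5_fisher &
    verdicts$c6_recurrent
  verdicts
}

#' Classify sites by cross-caller consensus
#'
#' Aggregates the per-caller verdicts for each (individual, site) and
#' classifies the site by the number of supporting callers (callers whose
#' verdict passed all criteria): `tissue_specific` when supported by at
#' least `min_callers_specific` callers, `possible` when supported by at
#' least `min_callers_possible` but fewer than `min_callers_specific`, and
#' `rejected` otherwise.
#'
#' @param verdicts A fully resolved verdict tibble (see [flag_recurrent()];
#'   an unresolved `c6_recurrent` of `NA` is treated as passing).
#' @param thresholds A [filter_thresholds()] object.
#' @return Tibble with one row per (individual, site): key columns,
#'   `supporting_callers` (comma-separated), `n_supporting` and
#'   `classification` (factor: `tissue_specific`, `possible`, `rejected`),
#'   ordered by chromosome, position, individual.
#' @export
consensus_classify <- function(verdicts, thresholds = filter_thresholds()) {
  key <- c("individual", "chrom", "pos", "ref", "alt")
  if (nrow(verdicts) == 0) {
    return(tibble::tibble(
      individual = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), supporting_callers = character(),
      n_supporting = integer(),
      classification = factor(character(),
                              levels = c("tissue_specific", "possible",
                                         "rejected"))))
  }
  dup <- verdicts |>
    dplyr::count(dplyr::across(dplyr::all_of(c(key, "caller")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate verdicts for caller %s at %s",
                  dup$caller[1],
                  locus_label(dup$chrom[1], dup$pos[1], dup$ref[1],
                              dup$alt[1])))
  }
  verdicts$.support <- verdicts$passed &
    (is.na(verdicts$c6_recurrent) | verdicts$c6_recurrent)
  out <- verdicts |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      supporting_callers = paste(sort(.data$caller[.data$.support]),
                                 collapse = ","),
      n_supporting = sum(.data$.support),
      .groups = "drop")
  out$classification <- classify_support(out$n_supporting, thresholds)
  dplyr::arrange(out, .data$chrom, .data$pos, .data$individual)
}

classify_support <- function(n_supporting, thresholds) {
  factor(
    dplyr::case_when(
      n_supporting >= thresholds$min_callers_specific ~ "tissue_specific",
      n_supporting >= thresholds$min_callers_possible ~ "possible",
      TRUE ~ "rejected"),
    levels = c("tissue_specific", "possible", "rejected"))
}

#' Run the full somatic screen on a cohort
#'
#' End-to-end screen over pooled per-caller call sets: caller-comment
#' exclusion, genomic masking, per-pair criteria, cohort-wide recurrence,
#' and cross-caller consensus classification.
#'
#' @param calls Pooled site-call tibble for the whole cohort (rows from all
#'   individuals and callers; bind the outputs of [read_vcf_calls()]).
#' @param mask Optional `genomic_mask` of excluded regions.
#' @param thresholds A [filter_thresholds()] object.
#' @param comment_patterns Disqualifying caller comments (see
#'   [exclude_commented_calls()]); `NULL` disables comment exclusion.
#' @param comment_applies_to Callers subject to comment exclusion.
#' @return A `somatic_screen` object: a list with `results` (consensus
#'   classifications), `verdicts` (per-caller criterion outcomes),
#'   `recurrent` (recurrent site keys), `summary` (per-caller raw candidate
#'   counts, per-class totals, attrition counts) and `thresholds`.
#' @export
run_pipeline <- function(calls, mask = NULL,
                         thresholds = filter_thresholds(),
                         comment_patterns = mutect_exclusion_patterns(),
                         comment_applies_to = c("mutect1", "mutect2")) {
  assert_site_calls(calls)
  calls <- tibble::as_tibble(calls)
  n_raw <- nrow(calls)
  per_caller_raw <- calls |> dplyr::count(.data$caller, name = "n_raw")

  if (!is.null(comment_patterns)) {
    calls <- exclude_commented_calls(calls, comment_patterns,
                                     comment_applies_to)
  }
  n_comment_excluded <- attr(calls, "n_comment_excluded") %||% 0L
  calls <- apply_mask(calls, mask)
  n_masked <- attr(calls, "n_masked") %||% 0L

  verdicts <- evaluate_criteria(calls, thresholds)
  recurrent <- find_recurrent(verdicts, thresholds)
  verdicts <- flag_recurrent(verdicts, thresholds, recurrent)
  verdicts <- dplyr::arrange(verdicts, .data$chrom, .data$pos,
                             .data$individual, .data$caller)
  results <- consensus_classify(verdicts, thresholds)

  summary <- list(
    per_caller_raw = per_caller_raw,
    per_class = results |> dplyr::count(.data$classification,
                                        name = "n_sites", .drop = FALSE),
    attrition = tibble::tibble(
      stage = c("raw", "comment_excluded", "masked", "passed_criteria",
                "recurrent_sites"),
      n = c(n_raw, n_comment_excluded, n_masked, sum(verdicts$passed),
            nrow(recurrent)))
  )
  structure(list(results = results, verdicts = verdicts,
                 recurrent = recurrent, summary = summary,
                 thresholds = thresholds),
            class = "somatic_screen")
}

#' @export
print.somatic_screen <- function(x, ...) {
  cat("Somatic tissue-specificity screen\n")
  cat(sprintf("  %d site calls from %d caller(s), %d individual(s)\n",
              nrow(x$verdicts), length(unique(x$verdicts$caller)),
              length(unique(x$verdicts$individual))))
  pc <- x$summary$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-16s %d\n", pc$classification[i], pc$n_sites[i]))
  }
  invisible(x)
}
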