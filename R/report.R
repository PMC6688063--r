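ANNOTATION_CATEGORIES <- c("exon", "UTR", "intron", "upstream", "intergenic")

#' Read a region annotation table
#'
#' Reads a tab-separated interval annotation with columns `chrom`, `start`,
#' `end` (0-based half-open), `label` (gene/feature name) and `category`
#' (one of `exon`, `UTR`, `intron`, `upstream`; positions outside every
#' interval are `intergenic`).
#'
#' @param path Path to the TSV file.
#' @return A tibble of annotation intervals.
#' @export
read_region_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("chrom", "start", "end", "label", "category")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    abort(sprintf("annotation %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(ann$category), ANNOTATION_CATEGORIES)
  if (length(bad) > 0) {
    abort(sprintf("unknown annotation categor%s: %s",
                  if (length(bad) > 1) "ies" else "y",
                  paste(bad, collapse = ", ")))
  }
  ann
}

#' Annotate candidate sites with a genomic-location category
#'
#' Assigns each site the category and feature label of the
#' highest-priority overlapping annotation interval (priority
#' `exon > UTR > intron > upstream`; ties broken by alphabetical label).
#' Sites overlapping nothing are `intergenic` with no label.
#'
#' @param results A tibble with `chrom` and 1-based `pos` columns
#'   (e.g. `somatic_screen$results`).
#' @param annotation Annotation intervals (see [read_region_annotation()]),
#'   or `NULL` for all-intergenic.
#' @return `results` with added `category` (factor over
#'   exon/UTR/intron/upstream/intergenic) and `feature` columns.
#' @export
annotate_location <- function(results, annotation = NULL) {
  results <- tibble::as_tibble(results)
  if (is.null(annotation) || nrow(annotation) == 0 || nrow(results) == 0) {
    results$category <- factor(rep("intergenic", nrow(results)),
                               levels = ANNOTATION_CATEGORIES)
    results$feature <- rep(NA_character_, nrow(results))
    return(results)
  }
  annotation <- annotation |>
    dplyr::mutate(priority = match(.data$category, ANNOTATION_CATEGORIES)) |>
    dplyr::arrange(.data$priority, .data$label)
  category <- rep("intergenic", nrow(results))
  feature <- rep(NA_character_, nrow(results))
  for (chr in unique(results$chrom)) {
    i <- which(results$chrom == chr)
    a <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (nrow(a) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = results$pos[i], width = 1L),
      IRanges::IRanges(start = a$start + 1L, end = a$end),
      select = "first")   # annotation rows are already priority-sorted
    hit <- !is.na(hits)
    category[i[hit]] <- a$category[hits[hit]]
    feature[i[hit]] <- a$label[hits[hit]]
  }
  results$category <- factor(category, levels = ANNOTATION_CATEGORIES)
  results$feature <- feature
  results
}

#' Summarize candidate counts by group and location
#'
#' Tabulates `possible`/`tissue_specific` candidates per cohort group (and
#' per location category when the results are annotated). Counts are
#' site-level: each (individual, site) contributes once.
#'
#' @param results Consensus results, optionally annotated by
#'   [annotate_location()].
#' @param groups A tibble mapping `individual` to `group`, or `NULL` if
#'   `results` already has a `group` column.
#' @return A tibble of candidate counts per group (x category), with
#'   zero rows for groups present in `groups` but without candidates
#'   filled in as 0.
#' @export
summarize_candidates <- function(results, groups = NULL) {
  results <- tibble::as_tibble(results)
  if (!is.null(groups)) {
    results <- dplyr::left_join(results, groups, by = "individual")
  }
  if (!"group" %in% names(results)) {
    abort("supply a `groups` table or a `group` column in `results`")
  }
  candidates <- results[results$classification %in%
                          c("possible", "tissue_specific"), , drop = FALSE]
  by <- c("group", if ("category" %in% names(results)) "category")
  all_groups <- if (!is.null(groups)) unique(groups$group) else
    unique(results$group)
  counts <- candidates |>
    dplyr::count(dplyr::across(dplyr::all_of(by)), name = "n_candidates",
                 .drop = FALSE)
  if (!"category" %in% by) {
    counts <- tibble::tibble(group = all_groups) |>
      dplyr::left_join(counts, by = "group") |>
      dplyr::mutate(n_candidates = dplyr::coalesce(.data$n_candidates, 0L))
  }
  dplyr::arrange(counts, dplyr::across(dplyr::all_of(by)))
}

#' @rdname tidy.somatic_screen
#' @export
glance.somatic_screen <- function(x, ...) {
  pc <- x$summary$per_class
  n_of <- function(cls) {
    sum(pc$n_sites[pc$classification == cls])
  }
  tibble::tibble(
    n_calls = nrow(x$verdicts),
    n_sites = nrow(x$results),
    n_individuals = length(unique(x$verdicts$individual)),
    n_callers = length(unique(x$verdicts$caller)),
    n_tissue_specific = n_of("tissue_specific"),
    n_possible = n_of("possible"),
    n_rejected = n_of("rejected"),
    n_recurrent_sites = nrow(x$recurrent))
}

#' Tidy a somatic screen
#'
#' `tidy()` returns the consensus results (one row per individual/site) or,
#' with `type = "verdicts"`, the per-caller criterion table. `glance()`
#' returns a one-row cohort summary.
#'
#' @param x A `somatic_screen` object from [run_pipeline()].
#' @param type `"results"` (default) or `"verdicts"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.somatic_screen <- function(x, type = c("results", "verdicts"), ...) {
  type <- match.arg(type)
  if (type == "results") x$results else x$verdicts
}

#' Plot consensus caller support for a somatic screen
#'
#' Bar chart of candidate sites by number of supporting callers, colored
#' by consensus class -- the screen's analogue of a caller-overlap plot:
#' singleton calls dominate, the consensus classes are rare.
#'
#' @param object A `somatic_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somatic_screen <- function(object, ...) {
  dat <- dplyr::count(object$results, .data$n_supporting,
                      .data$classification, name = "n_sites")
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$n_supporting),
                                    y = .data$n_sites,
                                    fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "supporting callers", y = "candidate sites",
                  fill = "consensus class") +
    ggplot2::theme_minimal()
}

#' Tidy and summarize ddPCR quantification results
#'
#' `tidy()` returns the per-sample quantification table; `glance()` a
#' one-row overview.
#'
#' @param x A `ddpcr_quant` tibble from [ddpcr_quantify()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ddpcr_quant <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.ddpcr_quant
#' @export
glance.ddpcr_quant <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x),
    n_qc_passed = sum(x$qc_passed),
    n_wells = sum(x$n_wells),
    median_fa = stats::median(x$fa, na.rm = TRUE))
}

#' Plot ddPCR fractional abundances with confidence intervals
#'
#' @param object A `ddpcr_quant` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddpcr_quant <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = 100 * .data$fa,
                                    color = .data$qc_passed)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = 100 * .data$fa_low,
                                        ymax = 100 * .data$fa_high),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "fractional abundance (%)",
                  color = "QC passed") +
    ggplot2::theme_minimal()
}
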