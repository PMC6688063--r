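#' Read a BED exclusion mask
#'
#' Reads a BED3+ file (0-based, half-open intervals) into a normalized
#' genomic mask: per-chromosome intervals are sorted and overlapping or
#' bookended intervals merged. Typical use is masking segmental-duplication
#' regions, where mismapping produces recurrent artifact calls.
#'
#' @param path Path to a BED file. `track`, `browser` and `#` lines are
#'   ignored.
#' @return A `genomic_mask` tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open). The total masked length is recorded in the
#'   `masked_length` attribute.
#' @export
read_bed_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(new_genomic_mask(tibble::tibble(
      chrom = character(), start = integer(), end = integer())))
  }
  line_no <- which(keep)
  fields <- stringr::str_split(trimws(lines[keep]), "[\t ]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    abort(sprintf("BED line %d has fewer than 3 columns in %s",
                  line_no[which(n_fields < 3)[1]], path))
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    abort(sprintf("invalid BED interval at line %d of %s (need 0 <= start < end)",
                  line_no[which(bad)[1]], path))
  }
  new_genomic_mask(tibble::tibble(chrom = chrom, start = start, end = end))
}

# Normalize (sort + merge) and class a mask tibble. Merging uses IRanges on
# 1-based closed coordinates, converted back to BED convention.
new_genomic_mask <- function(intervals) {
  merged <- intervals |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      tibble::tibble(start = IRanges::start(r) - 1L, end = IRanges::end(r))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)
  out <- tibble::new_tibble(merged, class = "genomic_mask")
  attr(out, "masked_length") <- sum(merged$end - merged$start)
  out
}

#' Construct a genomic mask from a data frame
#'
#' @param intervals Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open). Intervals are sorted and merged.
#' @return A `genomic_mask` tibble.
#' @export
genomic_mask <- function(intervals = NULL) {
  if (is.null(intervals)) {
    intervals <- tibble::tibble(chrom = character(), start = integer(),
                                end = integer())
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start < 0 | intervals$start >= intervals$end)) {
    abort("mask intervals must satisfy 0 <= start < end")
  }
  new_genomic_mask(tibble::as_tibble(intervals[c("chrom", "start", "end")]))
}

#' Remove calls falling in masked regions
#'
#' Drops site calls whose (1-based) position falls inside a mask interval.
#' A BED interval `[start, end)` masks a call at position `pos` iff
#' `start <= pos - 1 < end`. Chromosomes present in the calls but absent
#' from the mask under a different naming convention (`"chr1"` vs `"1"`)
#' trigger a warning and are left unmasked.
#'
#' @param calls A site-call tibble.
#' @param mask A `genomic_mask` (see [read_bed_mask()]), or `NULL` for no
#'   masking.
#' @return `calls` without masked rows; the number of removals is recorded
#'   in the `n_masked` attribute.
#' @export
apply_mask <- function(calls, mask) {
  assert_site_calls(calls)
  if (is.null(mask) || nrow(mask) == 0 || nrow(calls) == 0) {
    attr(calls, "n_masked") <- 0L
    return(calls)
  }
  call_chroms <- unique(calls$chrom)
  mask_chroms <- unique(mask$chrom)
  toggled <- ifelse(grepl("^chr", call_chroms),
                    sub("^chr", "", call_chroms),
                    paste0("chr", call_chroms))
  mismatch <- call_chroms[!(call_chroms %in% mask_chroms) &
                            toggled %in% mask_chroms]
  if (length(mismatch) > 0) {
    warn(sprintf(
      "chromosome naming mismatch between calls and mask for %s; these calls were not masked",
      paste(mismatch, collapse = ", ")))
  }
  masked <- rep(FALSE, nrow(calls))
  for (chr in intersect(call_chroms, mask_chroms)) {
    i <- which(calls$chrom == chr)
    m <- mask[mask$chrom == chr, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = calls$pos[i], width = 1L),
      IRanges::IRanges(start = m$start + 1L, end = m$end))
    masked[i[S4Vectors::queryHits(hits)]] <- TRUE
  }
  out <- calls[!masked, , drop = FALSE]
  attr(out, "n_masked") <- sum(masked)
  out
}
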