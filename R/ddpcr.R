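#' Read a ddPCR well table
#'
#' Reads a CSV of per-well droplet counts for a two-channel (mutant /
#' wild-type) rare-event assay. Expected columns: `sample_id`, `well_id`,
#' `accepted` (accepted droplets), `mut_positive`, `wt_positive`
#' (positive droplets per channel) and `input_mass_ng` (DNA loaded in the
#' well, ng).
#'
#' @param path Path to the CSV file.
#' @return A tibble of wells.
#' @export
read_ddpcr_wells <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("sample_id", "well_id", "accepted", "mut_positive",
                "wt_positive", "input_mass_ng")
  missing <- setdiff(required, names(wells))
  if (length(missing) > 0) {
    abort(sprintf("ddPCR well table %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  bad <- wells$mut_positive > wells$accepted |
    wells$wt_positive > wells$accepted |
    wells$mut_positive < 0 | wells$wt_positive < 0
  if (any(bad)) {
    abort(sprintf("well %s has positive-droplet counts outside [0, accepted]",
                  wells$well_id[which(bad)[1]]))
  }
  wells
}

#' Merge replicate ddPCR wells per sample
#'
#' Replicate wells of one assay are merged by summing droplet counts; the
#' merged counts (not per-well averages) drive all downstream Poisson
#' estimates. Input mass is summed across wells.
#'
#' @param wells A well tibble (see [read_ddpcr_wells()]).
#' @return One row per `sample_id`: `n_wells`, `accepted`, `mut_positive`,
#'   `wt_positive`, `input_mass_ng`, `min_well_accepted`.
#' @export
merge_wells <- function(wells) {
  if (nrow(wells) == 0) abort("at least one well is required")
  wells |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_wells = dplyr::n(),
      min_well_accepted = min(.data$accepted),
      accepted = sum(.data$accepted),
      mut_positive = sum(.data$mut_positive),
      wt_positive = sum(.data$wt_positive),
      input_mass_ng = sum(.data$input_mass_ng),
      .groups = "drop")
}

#' Rare-event assay acceptance QC
#'
#' A merged assay is accepted when (i) it has at least `min_positive`
#' mutant-positive droplets in total, (ii) every well has at least
#' `min_accepted_per_well` accepted droplets, and (iii) at least
#' `min_mass_ng` of DNA was analyzed.
#'
#' @param wells A well tibble.
#' @param min_positive Minimum merged mutant-positive droplets (default 3).
#' @param min_accepted_per_well Minimum accepted droplets per well
#'   (default 10000).
#' @param min_mass_ng Minimum total DNA input in ng (default 10).
#' @return One row per sample: `sample_id`, `qc_passed`, `qc_reasons`
#'   (semicolon-separated failure reasons, `""` when passed).
#' @export
ddpcr_qc <- function(wells, min_positive = 3, min_accepted_per_well = 10000,
                     min_mass_ng = 10) {
  merged <- merge_wells(wells)
  reasons <- purrr::pmap_chr(
    merged,
    function(mut_positive, min_well_accepted, input_mass_ng, ...) {
      r <- character()
      if (mut_positive < min_positive) {
        r <- c(r, sprintf("below minimum positive droplets (%d < %d)",
                          mut_positive, min_positive))
      }
      if (min_well_accepted < min_accepted_per_well) {
        r <- c(r, sprintf("a well has fewer than %d accepted droplets",
                          min_accepted_per_well))
      }
      if (input_mass_ng < min_mass_ng) {
        r <- c(r, sprintf("input mass %.3g ng below %.3g ng",
                          input_mass_ng, min_mass_ng))
      }
      paste(r, collapse = "; ")
    })
  tibble::tibble(sample_id = merged$sample_id,
                 qc_passed = !nzchar(reasons),
                 qc_reasons = reasons)
}

#' Poisson mean occupancy from positive-droplet counts
#'
#' In digital PCR, template molecules partition into droplets approximately
#' as Poisson, so the mean copies per droplet is recovered from the
#' positive fraction: `lambda = -ln(1 - positive/accepted)`. Saturation
#' (every droplet positive) makes the estimate infinite and raises an
#' error advising dilution. Vectorized.
#'
#' @param positive Positive droplet count(s).
#' @param accepted Accepted droplet count(s), >= 1.
#' @return Estimated mean copies per droplet.
#' @examples
#' lambda_hat(12642, 20000)  # ~1.0
#' @export
lambda_hat <- function(positive, accepted) {
  if (any(accepted < 1)) abort("accepted droplet count must be >= 1")
  if (any(positive < 0 | positive > accepted)) {
    abort("positive droplets must lie in [0, accepted]")
  }
  if (any(positive == accepted)) {
    abort("all droplets positive: assay saturated; dilute the sample and repeat")
  }
  -log1p(-positive / accepted)
}

# Delta-method variance of lambda_hat: p / (N * (1 - p)).
lambda_var <- function(positive, accepted) {
  p <- positive / accepted
  p / (accepted * (1 - p))
}

#' Fractional abundance of the mutant allele with 95% CI
#'
#' Point estimate `FA = lambda_mut / (lambda_mut + lambda_wt)` from merged
#' droplet counts, with a 95% confidence interval by delta-method
#' propagation: each channel's occupancy variance is
#' `p / (N (1 - p))` (with `p` the positive fraction and `N` the accepted
#' droplets), propagated through the ratio and clipped to `[0, 1]`.
#'
#' @param mut_positive,wt_positive Merged positive droplet counts per
#'   channel.
#' @param accepted Merged accepted droplet count.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble: `lambda_mut`, `lambda_wt`, `fa`, `fa_low`, `fa_high`.
#'   `fa` is `NA` when both channels are empty.
#' @export
fractional_abundance <- function(mut_positive, wt_positive, accepted,
                                 conf_level = 0.95) {
  lm_ <- lambda_hat(mut_positive, accepted)
  lw_ <- lambda_hat(wt_positive, accepted)
  tot <- lm_ + lw_
  fa <- ifelse(tot > 0, lm_ / tot, NA_real_)
  vm <- lambda_var(mut_positive, accepted)
  vw <- lambda_var(wt_positive, accepted)
  var_fa <- ifelse(tot > 0, (lw_^2 * vm + lm_^2 * vw) / tot^4, NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(var_fa)
  tibble::tibble(
    lambda_mut = lm_, lambda_wt = lw_, fa = fa,
    fa_low = pmax(0, fa - half), fa_high = pmin(1, fa + half))
}

#' Copies per microliter from mean droplet occupancy
#'
#' @param lambda Mean copies per droplet.
#' @param droplet_volume Droplet partition volume in nL (default 0.85, the
#'   standard droplet-generator partition volume).
#' @return Concentration in copies per microliter.
#' @export
concentration <- function(lambda, droplet_volume = 0.85) {
  if (any(droplet_volume <= 0)) abort("droplet volume must be positive")
  lambda / droplet_volume * 1000
}

#' Mutant-allele dilution as "1 in X"
#'
#' Reciprocal of the fractional abundance, rounded half away from zero to
#' an integer (0.39% -> 1 in 256). Zero or undefined abundance yields `NA`.
#'
#' @param fa Fractional abundance in `(0, 1]`.
#' @return Integer vector.
#' @export
one_in_x <- function(fa) {
  out <- rep(NA_integer_, length(fa))
  pos <- !is.na(fa) & fa > 0
  out[pos] <- as.integer(floor(1 / fa[pos] + 0.5))
  out
}

#' Cells represented by a DNA mass
#'
#' Diploid human cells carry ~6.6 pg of genomic DNA, so a bulk DNA mass
#' bounds the number of genomes sampled (4 ug -> 606,060 cells). The count
#' is truncated to a whole cell.
#'
#' @param mass_ug DNA mass in micrograms.
#' @param pg_per_cell DNA mass per diploid cell in pg (default 6.6).
#' @return Integer cell count.
#' @export
cells_from_mass <- function(mass_ug, pg_per_cell = 6.6) {
  if (any(mass_ug <= 0)) abort("mass must be positive")
  as.integer(trunc(mass_ug * 1e6 / pg_per_cell))
}

#' Haploid genome copies from a DNA mass
#'
#' A haploid human genome weighs ~3.3 pg, so `mass_ng * 1000 / 3.3`
#' approximates the number of haploid copies loaded into an assay, rounded
#' half away from zero.
#'
#' @param mass_ng DNA mass in nanograms.
#' @param pg_per_haploid Haploid genome mass in pg (default 3.3).
#' @return Integer copy count.
#' @export
haploid_copies_from_mass <- function(mass_ng, pg_per_haploid = 3.3) {
  if (any(mass_ng <= 0)) abort("mass must be positive")
  x <- mass_ng * 1000 / pg_per_haploid
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Quantify rare-event ddPCR assays
#'
#' Full merged-well quantification per sample: Poisson occupancy and
#' concentration per channel, fractional abundance with 95% CI, the
#' "1 in X" mutant dilution, haploid copies implied by the input mass, and
#' acceptance QC.
#'
#' @param wells A well tibble (see [read_ddpcr_wells()]).
#' @param droplet_volume Droplet partition volume in nL.
#' @param conf_level Confidence level for the fractional-abundance CI.
#' @inheritParams ddpcr_qc
#' @return A `ddpcr_quant` tibble, one row per sample: merged counts,
#'   `lambda_mut`, `lambda_wt`, `conc_mut`, `conc_wt` (copies/uL), `fa`,
#'   `fa_low`, `fa_high`, `one_in_x`, `haploid_copies`, `qc_passed`,
#'   `qc_reasons`.
#' @export
ddpcr_quantify <- function(wells, droplet_volume = 0.85, conf_level = 0.95,
                           min_positive = 3, min_accepted_per_well = 10000,
                           min_mass_ng = 10) {
  merged <- merge_wells(wells)
  qc <- ddpcr_qc(wells, min_positive, min_accepted_per_well, min_mass_ng)
  est <- fractional_abundance(merged$mut_positive, merged$wt_positive,
                              merged$accepted, conf_level)
  out <- dplyr::bind_cols(merged, est)
  out$conc_mut <- concentration(out$lambda_mut, droplet_volume)
  out$conc_wt <- concentration(out$lambda_wt, droplet_volume)
  out$one_in_x <- one_in_x(out$fa)
  out$haploid_copies <- haploid_copies_from_mass(out$input_mass_ng)
  out <- dplyr::left_join(out, qc, by = "sample_id")
  tibble::new_tibble(out, class = "ddpcr_quant")
}
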