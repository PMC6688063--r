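#' Simulation parameters for a synthetic paired cohort
#'
#' Bundles the parameters of the paired brain/blood count simulator. The
#' defaults emulate the statistical structure of an ultra-deep (~700x)
#' targeted screen of a 14-pair cohort (4 early-onset and 4 late-onset
#' affected individuals, 6 controls): rare somatic SNVs confined to brain
#' at 0.4-3% AAF, germline heterozygotes subject to capture-step allelic
#' imbalance that deflates the brain AAF, independent per-read sequencing
#' noise, and caller-specific detection and false-positive behavior.
#'
#' @param n_individuals Number of sample pairs (default 14).
#' @param groups Named integer vector partitioning the pairs into groups
#'   (default `c(EOAD = 4, LOAD = 4, control = 6)`); must sum to
#'   `n_individuals`. Somatic variants are planted only in non-control
#'   groups.
#' @param depth_mean Mean sequencing depth (default 698 reads).
#' @param depth_sem Across-individual standard error of the mean depth
#'   (default 23); individual mean depths are drawn from
#'   `Normal(depth_mean, depth_sem * sqrt(n_individuals))`.
#' @param depth_size Negative-binomial size (inverse dispersion) of
#'   per-site depth around the individual mean (default 20).
#' @param n_germline_het Germline heterozygous sites per individual.
#' @param n_somatic Brain-confined somatic sites per affected individual.
#' @param n_background Artifact-eligible background sites per individual.
#' @param somatic_aaf_range True somatic AAF range (default
#'   `c(0.004, 0.03)`).
#' @param artifact_aaf_range Brain alt-read rate range at systematic
#'   artifact sites (default `c(0.003, 0.015)`: artifact signal sits at
#'   and below the detection floor, weaker than most true somatics).
#' @param artifact_frac Fraction of background sites per individual that
#'   carry a *private* brain-side artifact signal visible to all callers
#'   (default 0.02); the remaining background sites produce alternative
#'   reads at `error_rate` only.
#' @param n_artifact_loci Number of *shared* artifact loci per cohort
#'   (default 6): fixed positions (e.g. mismapping hotspots) showing the
#'   artifact signal in a random subset of individuals, which is what the
#'   recurrence criterion exists to remove.
#' @param artifact_penetrance_range Range of the per-locus probability
#'   that a shared artifact locus is active in a given individual
#'   (default `c(0.3, 0.9)`).
#' @param error_rate Per-base alternative-read probability in unaffected
#'   tissue (default 2e-4).
#' @param imbalance_strength Log-scale spread of the per-site multiplicative
#'   capture-bias factor applied to the brain allele-sampling probability at
#'   germline sites (default 0.35; 0 disables the imbalance).
#' @param bias_somatic Apply the capture bias to somatic sites too
#'   (default `FALSE`).
#' @param region_size Size in bp of the simulated target region (default
#'   1e5; a scaled-down stand-in for a multi-megabase capture design).
#' @param caller_profiles Named list of per-caller profiles (see
#'   [default_caller_profiles()]).
#' @param seed Integer seed making the whole cohort reproducible.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_individuals = 14,
                       groups = c(EOAD = 4, LOAD = 4, control = 6),
                       depth_mean = 698,
                       depth_sem = 23,
                       depth_size = 20,
                       n_germline_het = 30,
                       n_somatic = 2,
                       n_background = 200,
                       somatic_aaf_range = c(0.004, 0.03),
                       artifact_aaf_range = c(0.003, 0.015),
                       artifact_frac = 0.02,
                       n_artifact_loci = 6,
                       artifact_penetrance_range = c(0.3, 0.9),
                       error_rate = 2e-4,
                       imbalance_strength = 0.35,
                       bias_somatic = FALSE,
                       region_size = 1e5,
                       caller_profiles = default_caller_profiles(),
                       seed = 1L) {
  stopifnot(sum(groups) == n_individuals,
            error_rate >= 0, error_rate <= 1,
            artifact_frac >= 0, artifact_frac <= 1,
            length(somatic_aaf_range) == 2,
            somatic_aaf_range[1] > 0, somatic_aaf_range[2] < 0.2,
            somatic_aaf_range[1] <= somatic_aaf_range[2],
            imbalance_strength >= 0, region_size >= 1000,
            depth_mean > 0, depth_size > 0)
  structure(list(
    n_individuals = as.integer(n_individuals), groups = groups,
    depth_mean = depth_mean, depth_sem = depth_sem, depth_size = depth_size,
    n_germline_het = as.integer(n_germline_het),
    n_somatic = as.integer(n_somatic),
    n_background = as.integer(n_background),
    somatic_aaf_range = somatic_aaf_range,
    artifact_aaf_range = artifact_aaf_range,
    artifact_frac = artifact_frac,
    n_artifact_loci = as.integer(n_artifact_loci),
    artifact_penetrance_range = artifact_penetrance_range,
    error_rate = error_rate,
    imbalance_strength = imbalance_strength,
    bias_somatic = bias_somatic,
    region_size = as.integer(region_size),
    caller_profiles = caller_profiles,
    seed = as.integer(seed)), class = "sim_params")
}

#' Default per-caller emulation profiles
#'
#' Each profile gives a logistic detection-sensitivity curve in brain
#' alternative-read depth (`sens_midpoint`, `sens_scale`, `sens_max`), an
#' expected number of caller-private false-positive calls per individual
#' (`fp_per_individual`), and comment-injection probabilities
#' (`p_excludable_comment` for the five disqualifying MuTect annotations;
#' `benign_comment` is the caller's habitual non-disqualifying FILTER
#' value). False-positive rates are caller-specific: aggressive callers
#' emit far more private low-depth calls than conservative ones, which is
#' what makes multi-caller consensus informative.
#'
#' @return Named list of caller profiles.
#' @export
default_caller_profiles <- function() {
  profile <- function(fp, benign, p_excl = 0) {
    list(sens_midpoint = 5, sens_scale = 1.5, sens_max = 0.98,
         fp_per_individual = fp, p_excludable_comment = p_excl,
         benign_comment = benign)
  }
  list(
    mutect1 = profile(3, "fstar_tumor_lod, possible_contamination", 0.03),
    mutect2 = profile(46, "t_lod_fstar", 0.03),
    strelka2 = profile(12, "LowEVS"),
    varscan2 = profile(38, "PASS")
  )
}

#' Caller profiles with perfect sensitivity and no false positives
#'
#' Every caller detects every site with at least one alternative brain
#' read, emits no false positives and injects no comments. Useful for
#' noise-free recovery tests where the screen must return exactly the
#' planted somatic set.
#'
#' @return Named list of caller profiles.
#' @export
perfect_caller_profiles <- function() {
  lapply(default_caller_profiles(), function(p) {
    p$sens_midpoint <- -Inf   # plogis(Inf) = 1: detect everything seen
    p$sens_max <- 1
    p$fp_per_individual <- 0
    p$p_excludable_comment <- 0
    p$benign_comment <- "PASS"
    p
  })
}

#' Simulate paired brain/blood counts for one individual
#'
#' Plants germline heterozygous, brain-confined somatic and background
#' sites at distinct random positions, then draws per-tissue depths from a
#' negative binomial around the individual's mean depth and alternative
#' read counts from binomials at the sites' true (bias- and noise-adjusted)
#' allele frequencies:
#'
#' * germline heterozygotes: true AAF 0.5 in both tissues; the brain
#'   sampling probability is multiplied by a per-site log-normal bias
#'   factor (unit median, spread `imbalance_strength`) capped at 1,
#'   emulating reference bias introduced at the capture/amplification step;
#' * somatic sites: true brain AAF drawn uniformly from
#'   `somatic_aaf_range`, true blood AAF 0; blood reads can still show
#'   alternative bases at `error_rate`;
#' * background sites: a fraction `artifact_frac` carry a private
#'   brain-side artifact signal (rate from `artifact_aaf_range`), the rest
#'   produce alternative reads at `error_rate` in both tissues;
#' * shared artifact loci (when `artifact_loci` is supplied, as
#'   [simulate_cohort()] does): each locus is active in this individual
#'   with its penetrance, showing its artifact rate in brain.
#'
#' @param params A [sim_params()] object.
#' @param individual Individual identifier.
#' @param group Group label; somatic sites are planted only when not
#'   `"control"`.
#' @param seed Optional seed applied locally for a reproducible single
#'   pair; when `NULL` the current RNG stream is used (as in
#'   [simulate_cohort()]).
#' @param artifact_loci Optional tibble of shared artifact loci (`pos`,
#'   `ref`, `alt`, `rate`, `penetrance`); see [simulate_cohort()].
#' @return A tibble with one row per planted site: identity columns,
#'   realized counts (`brain_ref`, `brain_alt`, `blood_ref`, `blood_alt`)
#'   and the ground truth (`class` in
#'   `somatic_brain`/`germline_het`/`artifact`/`background`,
#'   `true_brain_aaf`, `true_blood_aaf`).
#' @export
simulate_pair_counts <- function(params, individual, group = "EOAD",
                                 seed = NULL, artifact_loci = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      simulate_pair_counts(params, individual, group, seed = NULL,
                           artifact_loci = artifact_loci)))
  }
  n_som <- if (identical(group, "control")) 0L else params$n_somatic
  n_het <- params$n_germline_het
  n_bg <- params$n_background
  shared <- if (is.null(artifact_loci)) {
    tibble::tibble(pos = integer(), ref = character(), alt = character(),
                   rate = numeric(), penetrance = numeric())
  } else {
    artifact_loci[runif(nrow(artifact_loci)) < artifact_loci$penetrance, ,
                  drop = FALSE]
  }
  n_shared <- nrow(shared)
  n_total <- n_som + n_het + n_bg + n_shared
  if (n_total == 0) {
    return(empty_counts_table())
  }
  if (n_total > params$region_size / 2) {
    abort("region_size too small for the requested number of sites")
  }

  free <- setdiff(seq_len(params$region_size), shared$pos)
  pos <- sample(free, n_som + n_het + n_bg)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  class <- c(rep("germline_het", n_het), rep("somatic_brain", n_som),
             rep("background", n_bg))
  # Which background sites carry a private brain-side artifact signal
  is_artifact <- c(rep(FALSE, n_het + n_som),
                   runif(n_bg) < params$artifact_frac)
  class[is_artifact] <- "artifact"

  true_brain <- numeric(length(pos))
  true_blood <- numeric(length(pos))
  true_brain[class == "germline_het"] <- 0.5
  true_blood[class == "germline_het"] <- 0.5
  true_brain[class == "somatic_brain"] <-
    runif(n_som, params$somatic_aaf_range[1], params$somatic_aaf_range[2])
  true_brain[class == "artifact"] <-
    runif(sum(class == "artifact"),
          params$artifact_aaf_range[1], params$artifact_aaf_range[2])

  # Append the active shared artifact loci
  pos <- c(pos, shared$pos)
  ref <- c(ref, shared$ref)
  alt <- c(alt, shared$alt)
  class <- c(class, rep("artifact", n_shared))
  true_brain <- c(true_brain, shared$rate)
  true_blood <- c(true_blood, rep(0, n_shared))
  ord <- order(pos)
  pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]; class <- class[ord]
  true_brain <- true_brain[ord]; true_blood <- true_blood[ord]

  # Per-site multiplicative capture bias on the brain channel (unit median)
  bias <- rep(1, n_total)
  if (params$imbalance_strength > 0) {
    biased <- class == "germline_het" |
      (params$bias_somatic & class == "somatic_brain")
    bias[biased] <- rlnorm(sum(biased), meanlog = 0,
                           sdlog = params$imbalance_strength)
  }

  ind_depth <- max(50, rnorm(1, params$depth_mean,
                             params$depth_sem * sqrt(params$n_individuals)))
  draw_depth <- function(n) {
    pmax(1L, rnbinom(n, mu = ind_depth, size = params$depth_size))
  }
  brain_depth <- draw_depth(n_total)
  blood_depth <- draw_depth(n_total)

  p_brain <- pmin(1, pmax(true_brain * bias, 0) + params$error_rate)
  p_blood <- pmin(1, true_blood + params$error_rate)
  brain_alt <- rbinom(n_total, brain_depth, p_brain)
  blood_alt <- rbinom(n_total, blood_depth, p_blood)

  tibble::tibble(
    individual = individual, group = group,
    chrom = "chr1", pos = pos, ref = ref, alt = alt,
    brain_ref = brain_depth - brain_alt, brain_alt = brain_alt,
    blood_ref = blood_depth - blood_alt, blood_alt = blood_alt,
    class = class, true_brain_aaf = true_brain, true_blood_aaf = true_blood,
    capture_bias = bias)
}

empty_counts_table <- function() {
  tibble::tibble(
    individual = character(), group = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    brain_ref = integer(), brain_alt = integer(),
    blood_ref = integer(), blood_alt = integer(), class = character(),
    true_brain_aaf = numeric(), true_blood_aaf = numeric(),
    capture_bias = numeric())
}

#' Simulate a full paired cohort with ground truth
#'
#' Draws count tables for every individual in the cohort (see
#' [simulate_pair_counts()]) and emulates the four somatic callers on them
#' (see [emulate_callers()]). The whole chain is reproducible from
#' `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return A list with `counts` (the pooled per-site count/truth table --
#'   this is the cohort's truth table), `calls` (the pooled emulated
#'   site-call tibble across callers) and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, {
    group_labels <- rep(names(params$groups), params$groups)
    ids <- sprintf("pair%02d", seq_len(params$n_individuals))
    artifact_loci <- if (params$n_artifact_loci > 0) {
      bases <- c("A", "C", "G", "T")
      ref <- sample(bases, params$n_artifact_loci, replace = TRUE)
      tibble::tibble(
        pos = sample.int(params$region_size, params$n_artifact_loci),
        ref = ref,
        alt = vapply(ref, function(r) sample(setdiff(bases, r), 1),
                     character(1)),
        rate = runif(params$n_artifact_loci,
                     params$artifact_aaf_range[1],
                     params$artifact_aaf_range[2]),
        penetrance = runif(params$n_artifact_loci,
                           params$artifact_penetrance_range[1],
                           params$artifact_penetrance_range[2]))
    } else NULL
    counts <- purrr::map2_dfr(ids, group_labels, function(id, grp) {
      simulate_pair_counts(params, id, grp, artifact_loci = artifact_loci)
    })
    calls <- emulate_callers(counts, params)
    list(counts = counts, calls = calls, params = params)
  })
}

#' Emulate multi-caller detection on simulated counts
#'
#' Each emulated caller reports a site with probability given by its
#' logistic sensitivity curve in brain alternative-read depth (sites with
#' no alternative brain reads are never reported), adds caller-private
#' false-positive calls at random unplanted positions with low-depth
#' fabricated counts, and stamps its habitual FILTER comment --
#' occasionally one of the five disqualifying MuTect annotations.
#'
#' @param counts A count/truth table from [simulate_pair_counts()] or the
#'   pooled cohort table.
#' @param params A [sim_params()] object (uses `caller_profiles`,
#'   `region_size`, `depth_mean`).
#' @param seed Optional local seed; when `NULL` the current RNG stream is
#'   used.
#' @return A site-call tibble (columns as [read_vcf_calls()]) pooled over
#'   the four callers, with a `truth_class` column carried over from the
#'   simulation (`"caller_fp"` for fabricated calls).
#' @export
emulate_callers <- function(counts, params, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) {
    return(withr::with_seed(seed, emulate_callers(counts, params, seed = NULL)))
  }
  per_ind <- split(counts, counts$individual)
  purrr::map_dfr(names(params$caller_profiles), function(caller) {
    prof <- params$caller_profiles[[caller]]
    purrr::map_dfr(per_ind, function(tab) {
      emulate_one(tab, caller, prof, params)
    })
  })
}

emulate_one <- function(tab, caller, prof, params) {
  visible <- tab[tab$brain_alt >= 1, , drop = FALSE]
  p_detect <- prof$sens_max *
    plogis((visible$brain_alt - prof$sens_midpoint) / prof$sens_scale)
  detected <- visible[runif(nrow(visible)) < p_detect, , drop = FALSE]

  comment_for <- function(n) {
    excl <- runif(n) < prof$p_excludable_comment
    out <- rep(prof$benign_comment, n)
    out[excl] <- sample(mutect_exclusion_patterns(), sum(excl),
                        replace = TRUE)
    out
  }
  detected_calls <- tibble::tibble(
    individual = detected$individual, caller = caller,
    chrom = detected$chrom, pos = detected$pos,
    ref = detected$ref, alt = detected$alt,
    brain_ref = detected$brain_ref, brain_alt = detected$brain_alt,
    blood_ref = detected$blood_ref, blood_alt = detected$blood_alt,
    comments = comment_for(nrow(detected)),
    truth_class = detected$class)

  n_fp <- rpois(1, prof$fp_per_individual)
  if (n_fp > 0) {
    free <- setdiff(seq_len(params$region_size), tab$pos)
    pos <- sample(free, min(n_fp, length(free)))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    depth_b <- pmax(1L, rnbinom(length(pos), mu = params$depth_mean,
                                size = params$depth_size))
    depth_l <- pmax(1L, rnbinom(length(pos), mu = params$depth_mean,
                                size = params$depth_size))
    # Caller-private artifacts: plausible low-frequency brain-only signal
    fp_alt <- pmin(depth_b, 4L + rpois(length(pos), 3))
    blood_alt <- rbinom(length(pos), depth_l, params$error_rate)
    fp_calls <- tibble::tibble(
      individual = tab$individual[1], caller = caller,
      chrom = "chr1", pos = pos, ref = ref, alt = alt,
      brain_ref = depth_b - fp_alt, brain_alt = fp_alt,
      blood_ref = depth_l - blood_alt, blood_alt = blood_alt,
      comments = comment_for(length(pos)),
      truth_class = "caller_fp")
    detected_calls <- dplyr::bind_rows(detected_calls, fp_calls)
  }
  dplyr::arrange(detected_calls, .data$pos)
}

#' Score screen results against the simulation truth
#'
#' A planted somatic site counts as *detectable* when its realized counts
#' pass all per-pair filter criteria (depth, brain alternative depth, AAF
#' bounds, AAF ratio, exact test) -- these are pure functions of the
#' site's own counts, so a site failing them cannot be recovered by any
#' caller, while one passing them is lost only through caller detection or
#' consensus. Sensitivity is the fraction of detectable somatic sites
#' classified `possible` or `tissue_specific`; the false discovery rate is
#' the fraction of `possible`/`tissue_specific` calls whose truth is not a
#' planted somatic site.
#'
#' @param results Consensus results (`somatic_screen$results` or the
#'   tibble from [consensus_classify()]).
#' @param truth The cohort count/truth table (`simulate_cohort()$counts`).
#' @param thresholds A [filter_thresholds()] object (for the
#'   detectability criteria).
#' @return One-row tibble: `n_somatic`, `n_detectable`, `n_detected`,
#'   `sensitivity`, `n_called`, `n_false`, `fdr`, plus per-class false
#'   discovery rates `fdr_tissue_specific`, `fdr_possible`, and a nested
#'   `confusion` tibble of truth class vs classification.
#' @export
evaluate_recovery <- function(results, truth,
                              thresholds = filter_thresholds()) {
  key <- c("individual", "chrom", "pos", "ref", "alt")
  if (!all(key %in% names(results)) || !all(key %in% names(truth))) {
    abort("results and truth must both carry individual/chrom/pos/ref/alt")
  }
  if (nrow(results) > 0 &&
      !any(results$individual %in% truth$individual)) {
    abort("results and truth cover disjoint cohorts")
  }
  som <- truth[truth$class == "somatic_brain", , drop = FALSE]
  if (nrow(som) > 0) {
    som_verdict <- evaluate_criteria(
      dplyr::mutate(som[, c(key, "brain_ref", "brain_alt",
                            "blood_ref", "blood_alt")],
                    caller = "truth"),
      thresholds)
    detectable <- som[som_verdict$passed, , drop = FALSE]
  } else {
    detectable <- som
  }

  called <- results[results$classification %in%
                      c("possible", "tissue_specific"), , drop = FALSE]
  called <- dplyr::left_join(
    called, truth[, c(key, "class")], by = key)
  called$class[is.na(called$class)] <- "caller_fp"

  hit <- dplyr::semi_join(detectable, called, by = key)
  n_detectable <- nrow(detectable)
  n_called <- nrow(called)
  n_false <- sum(called$class != "somatic_brain")

  class_fdr <- function(cls) {
    sub <- called[called$classification == cls, , drop = FALSE]
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$class != "somatic_brain")
  }
  confusion <- called |>
    dplyr::count(.data$class, .data$classification, name = "n")

  tibble::tibble(
    n_somatic = nrow(som),
    n_detectable = n_detectable,
    n_detected = nrow(hit),
    sensitivity = if (n_detectable > 0) nrow(hit) / n_detectable else NA_real_,
    n_called = n_called,
    n_false = n_false,
    fdr = if (n_called > 0) n_false / n_called else NA_real_,
    fdr_tissue_specific = class_fdr("tissue_specific"),
    fdr_possible = class_fdr("possible"),
    confusion = list(confusion))
}

#' Write emulated call sets as VCF files
#'
#' Writes one VCF per (individual, caller) in the uniform synthetic
#' dialect: two sample columns (`BRAIN`, `BLOOD`) with `AD` allelic depths
#' and the call's comment in FILTER. Files round-trip losslessly through
#' [read_vcf_calls()] with `dialect = "synthetic"`.
#'
#' @param calls A site-call tibble.
#' @param dir Output directory (created if needed).
#' @return Tibble mapping `individual`, `caller` to the written `path`,
#'   invisibly.
#' @export
write_synthetic_vcfs <- function(calls, dir) {
  assert_site_calls(calls)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory %s", dir))
  }
  groups <- dplyr::group_split(dplyr::group_by(calls, .data$individual,
                                               .data$caller))
  index <- purrr::map_dfr(groups, function(g) {
    ind <- g$individual[1]
    caller <- g$caller[1]
    path <- file.path(dir, sprintf("%s_%s.vcf", ind, caller))
    write_one_vcf(g, path)
    tibble::tibble(individual = ind, caller = caller, path = path)
  })
  if (nrow(calls) == 0) {
    index <- tibble::tibble(individual = character(), caller = character(),
                            path = character())
  }
  invisible(index)
}

#' Write one call set as a synthetic-dialect VCF
#'
#' Single-file version of [write_synthetic_vcfs()]; an empty call table
#' produces a header-only VCF. Comment separators and internal spaces are
#' normalized to valid FILTER syntax (`;`-separated, underscores), which
#' the comment matcher treats as equivalent to the originals.
#'
#' @param calls A site-call tibble (one individual/caller).
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_one_vcf <- function(calls, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=somaticsieve-synthetic",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "BRAIN", "BLOOD", sep = "\t"))
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  filt <- ifelse(is.na(calls$comments) | !nzchar(calls$comments),
                 ".", gsub(" ", "_", gsub("[,;] *", ";", calls$comments)))
  records <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\t.\tAD:DP\t%d,%d:%d\t%d,%d:%d",
    calls$chrom, calls$pos, calls$ref, calls$alt, filt,
    calls$brain_ref, calls$brain_alt, calls$brain_ref + calls$brain_alt,
    calls$blood_ref, calls$blood_alt, calls$blood_ref + calls$blood_alt)
  writeLines(c(header, records), path)
  invisible(path)
}
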