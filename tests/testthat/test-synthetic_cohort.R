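noise_free_params <- function(seed, ...) {
  sim_params(seed = seed, error_rate = 0, imbalance_strength = 0,
             artifact_frac = 0, n_artifact_loci = 0,
             caller_profiles = perfect_caller_profiles(), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(sim_params(seed = 42, n_individuals = 4,
                                  groups = c(EOAD = 2, control = 2)))
  b <- simulate_cohort(sim_params(seed = 42, n_individuals = 4,
                                  groups = c(EOAD = 2, control = 2)))
  expect_identical(a$counts, b$counts)
  expect_identical(a$calls, b$calls)
  pair_a <- simulate_pair_counts(sim_params(), "p1", "EOAD", seed = 7)
  pair_b <- simulate_pair_counts(sim_params(), "p1", "EOAD", seed = 7)
  expect_identical(pair_a, pair_b)
})

test_that("noise-free somatic sites are brain-confined and control pairs are clean", {
  p <- noise_free_params(7, n_background = 0, n_germline_het = 0)
  counts <- simulate_pair_counts(p, "p1", "EOAD", seed = 7)
  expect_equal(nrow(counts), p$n_somatic)
  expect_true(all(counts$class == "somatic_brain"))
  expect_true(all(counts$brain_alt > 0))
  expect_true(all(counts$blood_alt == 0))
  ctrl <- simulate_pair_counts(p, "p2", "control", seed = 8)
  expect_equal(nrow(ctrl), 0)
})

test_that("capture imbalance deflates brain AAF at germline sites", {
  p <- sim_params(seed = 3, n_germline_het = 1000, n_somatic = 0,
                  n_background = 0, n_artifact_loci = 0,
                  imbalance_strength = 0.5, region_size = 1e5 * 5)
  counts <- simulate_pair_counts(p, "p1", "control", seed = 3)
  brain_aaf <- counts$brain_alt / (counts$brain_ref + counts$brain_alt)
  blood_aaf <- counts$blood_alt / (counts$blood_ref + counts$blood_alt)
  # log-normal bias has mean exp(s^2/2) but is capped at p = 1, deflating
  # the mean; more tellingly, brain AAFs spread far beyond binomial noise
  expect_equal(mean(blood_aaf), 0.5, tolerance = 0.01)
  expect_gt(sd(brain_aaf), 3 * sd(blood_aaf))
  # a 30-40% blood AAF paired with ~20% brain AAF is now a plausible draw
  expect_gt(mean(brain_aaf < 0.3), 0.1)
})

test_that("caller emulation respects degenerate sensitivity profiles", {
  p <- noise_free_params(5)
  sim <- simulate_cohort(p)
  # perfect profiles: every caller reports exactly the sites with alt reads
  visible <- sim$counts[sim$counts$brain_alt >= 1, ]
  for (clr in c("mutect1", "mutect2", "strelka2", "varscan2")) {
    sub <- sim$calls[sim$calls$caller == clr, ]
    expect_equal(nrow(sub), nrow(visible))
    expect_setequal(paste(sub$individual, sub$pos),
                    paste(visible$individual, visible$pos))
  }
  # a dead caller caps consensus support at 3
  profiles <- perfect_caller_profiles()
  profiles$strelka2$sens_max <- 0
  profiles$strelka2$sens_midpoint <- Inf
  p2 <- noise_free_params(5)
  p2$caller_profiles <- profiles
  sim2 <- simulate_cohort(p2)
  screen <- run_pipeline(sim2$calls, comment_patterns = NULL)
  expect_true(all(screen$results$n_supporting <= 3))
  expect_false(any(screen$results$classification == "tissue_specific"))
})

test_that("default caller profiles yield mostly singleton candidates", {
  sim <- simulate_cohort(sim_params(seed = 9))
  screen <- run_pipeline(sim$calls)
  passing <- screen$verdicts[screen$verdicts$passed, ]
  support <- dplyr::count(passing, individual, chrom, pos, ref, alt,
                          name = "support")
  n_single <- sum(support$support == 1)
  n_consensus <- sum(support$support >= 3)
  expect_gt(n_single, 10 * n_consensus)
})

test_that("recovery metrics hit the noise-free limits and boundary cases", {
  p <- noise_free_params(13)
  sim <- simulate_cohort(p)
  screen <- run_pipeline(sim$calls, comment_patterns = NULL)
  m <- evaluate_recovery(screen$results, sim$counts)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$fdr, 0.0)
  expect_gt(m$n_detectable, 0)
  # forcing brain alt depth below the filter floor empties the denominator
  low <- sim$counts
  low$brain_alt <- pmin(low$brain_alt, 4L)
  m2 <- evaluate_recovery(screen$results[0, ], low)
  expect_equal(m2$n_detectable, 0)
  expect_true(is.na(m2$sensitivity))
  # disjoint cohorts are an input error
  other <- sim$counts
  other$individual <- paste0("zz_", other$individual)
  expect_error(evaluate_recovery(screen$results, other), "disjoint")
})

test_that("tissue_specific consensus is purer than possible over seeds", {
  fdr_ts <- c(); fdr_poss <- c()
  for (s in 1:8) {
    sim <- simulate_cohort(sim_params(seed = s))
    screen <- run_pipeline(sim$calls)
    m <- evaluate_recovery(screen$results, sim$counts)
    fdr_ts <- c(fdr_ts, m$fdr_tissue_specific)
    fdr_poss <- c(fdr_poss, m$fdr_possible)
  }
  expect_lt(mean(fdr_ts, na.rm = TRUE), mean(fdr_poss, na.rm = TRUE))
})

test_that("raising the error rate raises blood alt counts in expectation", {
  mean_blood_alt <- vapply(c(0, 5e-4, 2e-3), function(e) {
    p <- sim_params(seed = 21, error_rate = e, n_background = 400,
                    n_germline_het = 0, n_somatic = 0, n_artifact_loci = 0,
                    artifact_frac = 0)
    counts <- simulate_pair_counts(p, "p1", "EOAD", seed = 21)
    mean(counts$blood_alt)
  }, numeric(1))
  expect_true(all(diff(mean_blood_alt) > 0))
})

test_that("planted somatic AAF is recovered with slope ~1 at depth 700x", {
  p <- sim_params(seed = 31, n_individuals = 1, groups = c(EOAD = 1),
                  n_somatic = 1000, n_germline_het = 0, n_background = 0,
                  n_artifact_loci = 0, region_size = 1e6,
                  depth_sem = 0)
  counts <- simulate_pair_counts(p, "p1", "EOAD", seed = 31)
  est <- counts$brain_alt / (counts$brain_alt + counts$brain_ref)
  fit <- stats::lm(est ~ 0 + counts$true_brain_aaf)
  expect_equal(unname(stats::coef(fit)[1]), 1, tolerance = 0.1)
})

test_that("synthetic VCFs round-trip losslessly and deterministically", {
  p <- sim_params(seed = 17, n_individuals = 2, groups = c(EOAD = 1,
                                                           control = 1),
                  n_background = 30, n_germline_het = 10)
  sim <- simulate_cohort(p)
  dir <- withr::local_tempdir()
  index <- write_synthetic_vcfs(sim$calls, dir)
  expect_true(all(file.exists(index$path)))
  for (i in seq_len(nrow(index))) {
    orig <- sim$calls[sim$calls$individual == index$individual[i] &
                        sim$calls$caller == index$caller[i], ]
    orig <- dplyr::arrange(orig, chrom, pos)
    back <- read_vcf_calls(index$path[i], "synthetic", index$individual[i])
    cols <- c("chrom", "pos", "ref", "alt", "brain_ref", "brain_alt",
              "blood_ref", "blood_alt")
    expect_equal(as.data.frame(back[cols]), as.data.frame(orig[cols]),
                 ignore_attr = TRUE)
  }
  # identical content under the same seed
  dir2 <- withr::local_tempdir()
  write_synthetic_vcfs(simulate_cohort(p)$calls, dir2)
  f1 <- sort(list.files(dir, full.names = TRUE))
  f2 <- sort(list.files(dir2, full.names = TRUE))
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  # an empty call table produces a header-only VCF
  hdr_only <- file.path(dir, "empty.vcf")
  write_one_vcf(sim$calls[0, ], hdr_only)
  expect_equal(nrow(read_vcf_calls(hdr_only, "synthetic", "p0")), 0)
})
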