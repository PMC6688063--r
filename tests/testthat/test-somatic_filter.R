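test_that("AAF matches the printed percentages and rejects zero depth", {
  expect_equal(aaf(582, 6), 6 / 588)
  expect_equal(round(100 * aaf(582, 6), 1), 1.0)
  expect_equal(round(100 * aaf(221, 6), 1), 2.6)
  expect_equal(aaf(100, 0), 0)
  expect_error(aaf(0, 0), "zero total depth")
  expect_error(aaf(-1, 5), ">= 0")
})

test_that("AAF ratio uses the rare-variant conventions", {
  brain <- aaf(1001, 10); blood <- aaf(1477, 1)
  expect_equal(aaf_ratio(brain, blood), brain / blood, tolerance = 1e-12)
  expect_gt(aaf_ratio(brain, blood), 1.2)  # outside the exclusion window
  expect_identical(aaf_ratio(0.01, 0), Inf)
  expect_true(is.nan(aaf_ratio(0, 0)))
  expect_equal(aaf_ratio(0.10, 0.10), 1.0)
})

test_that("exact test agrees with brute-force enumeration (property, totals <= 500)", {
  withr::local_seed(20240917)
  tables <- random_tables(150, max_total = 500)
  for (side in c("two_sided_minlik", "one_sided_brain_enriched")) {
    p_pkg <- fisher_exact(tables[, 1], tables[, 2], tables[, 3], tables[, 4],
                          sidedness = side)
    p_oracle <- vapply(seq_len(nrow(tables)), function(i) {
      oracle_fisher(tables[i, 1], tables[i, 2], tables[i, 3], tables[i, 4],
                    side)
    }, numeric(1))
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10, info = side)
  }
})

test_that("exact test reproduces the validated-site p-values", {
  expect_equal(fisher_exact(10, 997, 0, 1472), 1.191117e-4,
               tolerance = 1e-5)
  expect_equal(fisher_exact(5, 396, 0, 409), 0.0293628, tolerance = 1e-5)
  expect_lt(fisher_exact(5, 396, 0, 409), 0.05)
  expect_equal(fisher_exact(0, 100, 0, 100), 1.0)
  expect_equal(fisher_exact(0, 100, 0, 100, "one_sided_brain_enriched"), 1.0)
  expect_error(fisher_exact(-1, 10, 0, 10), ">= 0")
})

test_that("one-sided p is non-increasing in brain alt depth (fixed other cells)", {
  p <- fisher_exact(0:12, 600, 2, 700, sidedness = "one_sided_brain_enriched")
  expect_true(all(diff(p) <= 1e-12))
})

test_that("criteria evaluate as written, all recorded without short-circuit", {
  th <- filter_thresholds()
  calls <- tibble::tibble(
    individual = "p1", caller = "mutect1", chrom = "chr1",
    pos = c(207461994L, 2L, 3L, 4L), ref = "C", alt = "T",
    brain_ref = c(582L, 50L, 400L, 30L),
    brain_alt = c(6L, 30L, 4L, 5L),
    blood_ref = c(794L, 60L, 400L, 30L),
    blood_alt = c(0L, 28L, 0L, 0L),
    comments = "")
  v <- evaluate_criteria(calls, th)
  # validated site: all five pass
  first <- v[v$pos == 207461994L, ]
  expect_true(all(unlist(
    first[c("c1_depth", "c2_brain_alt", "c3_aaf", "c4_ratio", "c5_fisher")])))
  expect_true(first$passed)
  # germline-like heterozygote fails the AAF bound
  het <- v[v$pos == 2L, ]
  expect_false(het$c3_aaf)
  expect_false(het$passed)
  expect_true(het$c1_depth)  # still evaluated and recorded
  # boundary: 4 alt reads is below the minimum of 5
  expect_false(v$c2_brain_alt[v$pos == 3L])
  # depth 35 in both tissues fails the 50x requirement, rest recorded
  low <- v[v$pos == 4L, ]
  expect_false(low$c1_depth)
  expect_true(low$c2_brain_alt)
})

test_that("threshold boundaries are strict/non-strict exactly as defined", {
  th <- filter_thresholds()
  base <- tibble::tibble(
    individual = "p1", caller = "mutect1", chrom = "chr1", pos = 1L,
    ref = "C", alt = "T", comments = "")
  # depth exactly 50 in both tissues passes c1; alt exactly 5 passes c2
  v <- evaluate_criteria(dplyr::mutate(base, brain_ref = 45L, brain_alt = 5L,
                                       blood_ref = 50L, blood_alt = 0L), th)
  expect_true(v$c1_depth & v$c2_brain_alt)
  # brain AAF exactly 20% fails the strict bound
  v <- evaluate_criteria(dplyr::mutate(base, brain_ref = 80L, brain_alt = 20L,
                                       blood_ref = 100L, blood_alt = 0L), th)
  expect_false(v$c3_aaf)
  # ratio exactly at the window edge is excluded (closed interval);
  # AAFs 1/4 and 5/16 are exactly representable, so the quotient is the
  # same double as the 0.8 threshold
  v <- evaluate_criteria(dplyr::mutate(base, brain_ref = 12L, brain_alt = 4L,
                                       blood_ref = 11L, blood_alt = 5L), th)
  expect_identical(v$aaf_ratio, 0.8)
  expect_false(v$c4_ratio)
  # ratio of 1 (identical AAFs) sits inside the window
  v <- evaluate_criteria(dplyr::mutate(base, brain_ref = 90L, brain_alt = 10L,
                                       blood_ref = 90L, blood_alt = 10L), th)
  expect_false(v$c4_ratio)
})

test_that("recurrent sites are found across individuals and fail everywhere", {
  th <- filter_thresholds()
  calls <- tibble::tibble(
    individual = rep(c("p1", "p2", "p3"), each = 2),
    caller = "varscan2", chrom = "chr1",
    pos = c(100L, 200L, 100L, 300L, 400L, 500L),
    ref = "C", alt = "T",
    brain_ref = 600L, brain_alt = 7L, blood_ref = 600L, blood_alt = 0L,
    comments = "")
  v <- evaluate_criteria(calls, th)
  rec <- find_recurrent(v, th)
  expect_equal(rec$pos, 100L)
  expect_equal(rec$n_individuals, 2L)
  v <- flag_recurrent(v, th, rec)
  expect_false(any(v$passed[v$pos == 100L]))
  expect_true(all(v$passed[v$pos != 100L]))
  # a single-individual site is not recurrent; empty input yields no keys
  expect_equal(nrow(find_recurrent(v[v$pos == 200L, ], th)), 0)
  expect_equal(nrow(find_recurrent(v[0, ], th)), 0)
})

test_that("consensus classes follow caller support and reject duplicates", {
  th <- filter_thresholds()
  verdict_set <- function(n_pass) {
    tibble::tibble(
      individual = "p1", chrom = "chr1", pos = 1L, ref = "C", alt = "T",
      caller = c("mutect1", "mutect2", "strelka2", "varscan2"),
      c1_depth = TRUE, c2_brain_alt = TRUE, c3_aaf = TRUE, c4_ratio = TRUE,
      c5_fisher = TRUE, c6_recurrent = TRUE,
      passed = c(rep(TRUE, n_pass), rep(FALSE, 4 - n_pass)))
  }
  cls <- function(n) as.character(
    consensus_classify(verdict_set(n), th)$classification)
  expect_equal(cls(4), "tissue_specific")
  expect_equal(cls(3), "possible")
  expect_equal(cls(2), "rejected")
  expect_equal(cls(0), "rejected")
  dup <- dplyr::bind_rows(verdict_set(4), verdict_set(4)[1, ])
  expect_error(consensus_classify(dup, th), "duplicate")
})

test_that("consensus is monotone: adding a passing caller never downgrades", {
  th <- filter_thresholds()
  rank <- c(rejected = 1, possible = 2, tissue_specific = 3)
  for (n in 0:3) {
    v <- tibble::tibble(
      individual = "p1", chrom = "chr1", pos = 1L, ref = "C", alt = "T",
      caller = c("mutect1", "mutect2", "strelka2", "varscan2")[seq_len(n + 1)],
      c1_depth = TRUE, c2_brain_alt = TRUE, c3_aaf = TRUE, c4_ratio = TRUE,
      c5_fisher = TRUE, c6_recurrent = TRUE,
      passed = c(rep(TRUE, n), FALSE))
    before <- rank[[as.character(consensus_classify(v, th)$classification)]]
    v$passed[n + 1] <- TRUE
    after <- rank[[as.character(consensus_classify(v, th)$classification)]]
    expect_gte(after, before)
  }
})

test_that("a germline-range AAF can never reach possible/tissue_specific", {
  th <- filter_thresholds()
  withr::local_seed(7)
  for (i in 1:50) {
    depth_b <- sample(50:1200, 1); depth_l <- sample(50:1200, 1)
    brain_alt <- rbinom(1, depth_b, runif(1, 0.20, 0.6))
    calls <- tibble::tibble(
      individual = "p1", chrom = "chr1", pos = 1L, ref = "C", alt = "T",
      caller = c("mutect1", "mutect2", "strelka2", "varscan2"),
      brain_ref = depth_b - brain_alt, brain_alt = brain_alt,
      blood_ref = depth_l, blood_alt = 0L, comments = "")
    calls$brain_alt <- pmax(calls$brain_alt, ceiling(0.2 * depth_b))
    calls$brain_ref <- depth_b - calls$brain_alt
    res <- consensus_classify(flag_recurrent(evaluate_criteria(calls, th), th),
                              th)
    expect_equal(as.character(res$classification), "rejected")
  }
})

test_that("blood-absent variants pass the ratio criterion by convention", {
  th <- filter_thresholds()
  calls <- tibble::tibble(
    individual = "p1", caller = "mutect1", chrom = "chr1", pos = 1L,
    ref = "C", alt = "T", brain_ref = 600L, brain_alt = 6L,
    blood_ref = 700L, blood_alt = 0L, comments = "")
  v <- evaluate_criteria(calls, th)
  expect_identical(v$aaf_ratio, Inf)
  expect_true(v$c4_ratio)
})

test_that("run_pipeline is invariant to record and caller ordering", {
  sim <- simulate_cohort(sim_params(seed = 11, n_individuals = 4,
                                    groups = c(EOAD = 2, control = 2),
                                    n_background = 40, n_germline_het = 10))
  calls <- sim$calls
  screen1 <- run_pipeline(calls)
  screen2 <- run_pipeline(calls[sample.int(nrow(calls)), ])
  expect_equal(screen1$results, screen2$results)
  expect_equal(screen1$verdicts, screen2$verdicts)
})

test_that("an empty cohort yields an empty, zeroed screen", {
  empty <- brain_snv_candidates()[0, ]
  screen <- run_pipeline(empty)
  expect_equal(nrow(screen$results), 0)
  expect_equal(sum(screen$summary$per_class$n_sites), 0)
})
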