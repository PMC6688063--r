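# Independent brute-force oracle for the exact test: enumerate every 2x2
# table with the observed margins and sum hypergeometric point
# probabilities. Kept free of any package code path.
oracle_fisher <- function(brain_alt, brain_ref, blood_alt, blood_ref,
                          sidedness = "two_sided_minlik") {
  k <- brain_alt + blood_alt          # total alternative reads
  m <- brain_alt + brain_ref          # brain margin
  n <- blood_alt + blood_ref          # blood margin
  xs <- max(0, k - n):min(k, m)       # feasible brain-alt cells
  probs <- dhyper(xs, m, n, k)
  if (sidedness == "two_sided_minlik") {
    obs <- dhyper(brain_alt, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  } else {
    sum(probs[xs >= brain_alt])
  }
}

# Random 2x2 allele-count tables with bounded totals.
random_tables <- function(n, max_total = 500) {
  t(vapply(seq_len(n), function(i) {
    total <- sample.int(max_total - 4, 1) + 4
    brain <- sample.int(total - 1, 1)
    blood <- total - brain
    brain_alt <- rbinom(1, brain, runif(1, 0, 0.3))
    blood_alt <- rbinom(1, blood, runif(1, 0, 0.3))
    c(brain_alt = brain_alt, brain_ref = brain - brain_alt,
      blood_alt = blood_alt, blood_ref = blood - blood_alt)
  }, numeric(4)))
}
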