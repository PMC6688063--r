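---
title: "Screening paired brain/blood sequencing for tissue-specific somatic SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening paired brain/blood sequencing for tissue-specific somatic SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticsieve)
library(dplyr)
```

## The screening model

A mosaic SNV confined to one tissue shows up in bulk sequencing as a small
excess of alternative reads in that tissue and (ideally) none in a matched
reference tissue from the same individual. At ~700× depth a 1% variant
yields on the order of 7 alternative reads — enough to observe, but in the
same range as recurrent sequencing and alignment artifacts. The screen
therefore never trusts any single signal:

1. somatic callers are run in tumor/normal mode (affected tissue as
   "tumor") with their default somatic filtering *disabled*, because those
   defaults are tuned for tumor allele fractions and remove most genuine
   low-frequency mosaic variants;
2. an explicit count-based filter is applied uniformly to every caller's
   raw candidate list;
3. only sites that several callers agree on survive.

### The per-pair filter

For one site in one individual under one caller, with brain counts
$(r_b, a_b)$ and blood counts $(r_l, a_l)$ and
$\mathrm{AAF} = a/(r+a)$:

| criterion | rule | default | rationale |
|---|---|---|---|
| 1 | $r_b+a_b \ge d_{\min}$ and $r_l+a_l \ge d_{\min}$ | $d_{\min}=50$ | below ~50× a 1% variant is indistinguishable from noise |
| 2 | $a_b \ge a_{\min}$ | $a_{\min}=5$ | a detection floor in absolute reads, not frequency |
| 3 | both AAFs $< f_{\max}$ | $f_{\max}=0.20$ | removes germline heterozygotes even when capture bias deflates one tissue's AAF well below 50% |
| 4 | $\mathrm{AAF}_b/\mathrm{AAF}_l \notin [0.8, 1.2]$ (closed) | — | near-equal frequencies indicate shared (germline or artifact) signal |
| 5 | Fisher exact $p < \alpha$ on $[[a_b,r_b],[a_l,r_l]]$ | $\alpha=0.05$ | the counts must differ beyond sampling noise |
| 6 | site not recurrent across individuals | >1 individual | independent recurrence of a rare somatic event is implausible; recurrent passes indicate a systematic artifact |

All comparisons are exactly as stated: "minimum 5" is $\ge 5$, the AAF
bound and $\alpha$ are strict, the ratio window is closed. Criterion 1's
"both samples" means the two samples of the individual's pair — the filter
is defined per pair, and callers only ever see the pair.

Two conventions deserve emphasis:

* **Ratio with zero blood AAF.** When $a_l = 0$ the ratio is $+\infty$,
  which lies outside the exclusion window: absence in blood is the
  strongest somatic evidence, not a degenerate case. Both AAFs zero cannot
  reach criterion 4 in practice (criterion 2 already failed), but is
  defined to fail it.
* **Fisher sidedness.** The two-sided minimum-likelihood convention (sum
  of all equally-or-less-likely tables with the observed margins, the
  convention implemented by `stats::fisher.test`) is the default. On the
  eleven bundled validated count pairs it passes all rows at
  $\alpha = 0.05$; doubling the one-sided tail instead would push two rows
  (p ≈ 0.059–0.060) over the threshold, which contradicts their validated
  status. A one-sided brain-enriched alternative is available via
  `filter_thresholds(fisher_sidedness = "one_sided_brain_enriched")` for
  users who prefer the directional hypothesis.

Criteria are always all evaluated (no short-circuiting) so the verdict
table can be audited per criterion; `passed` is their conjunction.
Recurrence is counted on sites passing criteria 1–5, before consensus, and
the threshold (more than one individual) is deliberately the weakest
reading of "recurrent" — both are configurable.

### Consensus

Callers' support sets are combined per (individual, site): support by all
four callers yields `tissue_specific`, by at least three `possible`,
otherwise `rejected`. Classification is monotone in support by
construction. Caller FILTER annotations such as `t_lod_fstar` or `LowEVS`
never reject a call — only the five MuTect artifact comments (`clustered
events`, `poor mapping region`, `nearby gap`, `triallelic sites`, `strand
artifact`) do, matched case-insensitively with spaces/underscores
equivalent, and only for the MuTect callers. Segmental-duplication masking
uses BED half-open intervals; internally all positions are 1-based and the
conversion happens only at the mask boundary, so a call at position $p$ is
masked iff some interval $[s, e)$ has $s \le p-1 < e$.

## ddPCR quantification

Rare-event ddPCR partitions a reaction into ~nanoliter droplets; with $k$
positive droplets out of $N$ accepted, the mean copies per droplet is the
Poisson inversion $\hat\lambda = -\ln(1 - k/N)$. Replicate wells are merged
by *summing* droplet counts before estimation. The mutant fractional
abundance is $\mathrm{FA} = \lambda_m/(\lambda_m+\lambda_w)$.

The 95% CI uses delta-method propagation: each channel's occupancy
variance is $\widehat{\mathrm{var}}(\hat\lambda) = p/(N(1-p))$ with
$p = k/N$, propagated through the ratio and clipped to $[0,1]$. The
instrument vendors' exact CI algorithm is proprietary, so the package
asserts *calibration* rather than equality: across 1000 simulated
droplet-level replicates at a true FA of 0.39% (~45,700 copies over two
wells), the CI covers the truth in ≥93% of runs (measured ~94%).

Other defaults and their provenance:

* droplet partition volume 0.85 nL (the standard droplet-generator
  partition volume; the conversion to copies/µL is
  $\lambda/V \times 1000$);
* QC: ≥3 merged mutant-positive droplets, ≥10,000 accepted droplets per
  well, ≥10 ng DNA analyzed;
* "1 in X" is $\mathrm{round}(1/\mathrm{FA})$ with half-away-from-zero
  rounding — the convention that reproduces all three published example
  values (256.4→256, 943.4→943, 1030.9→1031); base R's banker's rounding
  would not;
* mass arithmetic uses 6.6 pg per diploid cell (truncated: 4 µg represents
  606,060 cells) and 3.3 pg per haploid genome (rounded). Published
  "total haploid copies" values are instrument measurements and are not
  recomputed from mass — 151 ng converts to 45,758 copies, while the
  matching published figure is 45,740.

## The synthetic cohort generator

No raw data are deposited with studies of this kind, so the package ships
a generator that emulates the *statistical structure* of the screen and
carries its own ground truth. Defaults mirror the study conditions: 14
pairs (4 early-onset, 4 late-onset, 6 controls), mean depth 698× with an
across-individual spread of ±23 (SEM scale), somatic AAFs uniform in
0.4–3% confined to affected-group brains, per-base error 2×10⁻⁴.

Per individual it plants, at distinct random positions in a scaled-down
100 kb region:

* **germline heterozygotes** (default 30): true AAF 0.5 in both tissues;
  the brain sampling probability is multiplied by a per-site log-normal
  capture-bias factor (unit median, log-sd 0.35, capped so probabilities
  stay in $[0,1]$). This emulates the observed capture/amplification-step
  allelic imbalance in which variants at 30–40% AAF in blood can drop to
  ~20% in brain; at log-sd 0.35 such deflations are about a 1-sd draw.
  The distribution shape is a modeling choice — the imbalance is only
  characterized by examples, not a fitted distribution.
* **somatic sites** (default 2 per affected pair, matching ~11 candidates
  across 8 affected individuals): brain-confined; blood shows alternative
  reads only through the error rate.
* **background sites** (default 200): pure error-rate noise, of which a
  small fraction (2%) carry a *private* brain-side artifact signal at
  0.3–1.5% — weaker on average than true somatics.
* **shared artifact loci** (default 6 per cohort): fixed positions active
  in a random subset of individuals (penetrance 0.3–0.9 per locus),
  emulating mismapping hotspots. These are what the recurrence criterion
  exists to remove, and most are removed by it.

Depth is negative-binomial (size 20) around a per-individual mean drawn
from $\mathcal{N}(698, 23\sqrt{14})$ — the study reports only the
across-individual mean ± SEM, so the per-site dispersion is a package
choice typical of hybrid-capture data.

**Caller emulation.** Each caller reports a visible site (≥1 alternative
brain read) with probability
$s_{\max}\,\mathrm{logistic}((a_b - m)/w)$; defaults $m = 5$, $w = 1.5$,
$s_{\max} = 0.98$ place the detection floor near 5 alternative reads,
where all the published candidate SNVs sit. Each caller also fabricates
private false-positive calls at caller-specific rates (3, 46, 12 and 38
per pair for MuTect1, MuTect2, Strelka2, VarScan2 — proportional to the
published per-caller raw candidate totals 39/644/172/527 over 14 pairs)
and stamps its habitual FILTER comment, occasionally an excludable MuTect
artifact annotation. None of this claims to match the real callers'
internal statistics; it reproduces the *shape* that makes consensus
informative — under default profiles, singleton candidates outnumber
≥3-caller candidates by more than an order of magnitude, and the
tissue-specific class is purer than the possible class over repeated
simulations.

**Recovery scoring.** A planted somatic site counts as *detectable* when
its realized counts pass criteria 1–5 — all five are pure functions of
the site's own counts, so a site failing them is unrecoverable by any
caller no matter how sensitive, while one passing them can only be lost
to caller detection or consensus. (Restricting the definition to criteria
1–3 would let boundary sites — 5 alternative reads with an unfavorable
depth split between the tissues — fail the exact test and masquerade as
"missed" detections; under the adopted definition, noise-free runs with
perfect callers achieve sensitivity exactly 1 and FDR exactly 0, a
provable property the test suite asserts.) Sensitivity is reported over
detectable sites; FDR over all `possible`/`tissue_specific` calls, also
per class.

What passing the synthetic suite does **not** show: the generator has no
read-level errors (no strand bias, no mapping ambiguity, no UMI/duplicate
structure), no indels or multi-allelic sites, independent per-read errors
only, and emulated callers that share the simulated counts rather than
re-estimating them from reads. Results on real data depend on upstream
alignment quality in ways these tests cannot probe.

## Numerical choices and degenerate inputs

* AAF at zero total depth is an error, not `NaN`; the VCF readers never
  produce such rows.
* `aaf_ratio(0, 0)` is `NaN` and fails criterion 4 explicitly.
* Exact tests are computed once per distinct 2×2 table and joined back,
  which makes cohort-scale screens cheap.
* Verdict and result tables are sorted (chromosome, position, individual,
  caller), so outputs are invariant to input ordering.
* λ at droplet saturation (all droplets positive) is an error advising
  dilution rather than `Inf`.
* The whole generate→emulate→filter→score chain is reproducible from a
  single integer seed (`sim_params(seed = )`).
* Problem sizes in the test suite — 14-pair cohorts with ~250 planted
  sites per pair, 1000-replicate CI calibration, 100-150-table exact-test
  property sweeps — were chosen so the full suite exercises every module
  end-to-end in about a minute.

## A compact end-to-end run

```{r example, eval = FALSE}
sim    <- simulate_cohort(sim_params(seed = 1))
screen <- run_pipeline(sim$calls)
glance(screen)
evaluate_recovery(tidy(screen), sim$counts)
autoplot(screen)
```

## Limitations

* The screen is count-based: it cannot rescue variants the callers never
  report, and it inherits caller biases at the detection floor.
* No multiple-testing correction is applied beyond the fixed α — the
  published design used a fixed 0.05 threshold, and the consensus and
  recurrence criteria carry the burden of specificity.
* CNVs, indels and multi-allelic sites are out of scope.
* The delta-method CI is an approximation; at very low positive counts
  (< 3 droplets) it under-covers, which is exactly the regime the QC
  minimum-positive rule excludes.
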