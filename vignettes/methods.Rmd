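---
title: "Methods: exact trial statistics and survival-quartile genomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact trial statistics and survival-quartile genomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialomics)
```

trialomics implements the translational analysis of a single-arm phase II
oncology trial with paired genomic (targeted-panel) and transcriptomic
(bulk count) profiling. This vignette is the package's account of the
statistics it computes, the conventions it fixes where the field leaves
room, and what its synthetic-cohort tests do and do not demonstrate.

## Exact response statistics

The primary endpoint of a single-arm activity trial is a binomial
proportion. Two exact tools cover it:

**Clopper-Pearson limits.** For `x` responders of `n`, the two-sided
`1 - α` interval is `[qbeta(α/2; x, n-x+1), qbeta(1-α/2; x+1, n-x)]`,
with the lower bound exactly 0 when `x = 0` and the upper exactly 1 when
`x = n`. Coverage is conservative (≥ nominal) by construction; the test
suite verifies this *exactly*, by summing binomial mass over all
outcomes on a grid of `(n ≤ 30, p)`, rather than by simulation.
Percentages are rendered to one decimal with ties rounded away from
zero (`round_half_away()`), the convention of clinical response tables.

**A'Hern one-stage design.** `ahern_min_responses(n, p0, alpha)` finds
the smallest integer `r` with exact binomial tail
`P(X ≥ r | n, p0) ≤ α`, by tail summation — no normal approximation —
and `exact_power(n, r, p1)` gives the exact power at the alternative.
At the design point used throughout the examples (`n = 73, p0 = 0.66,
p1 = 0.80, α = 0.05` one-sided) the rule is ≥ 56 responses, with
attained alpha 0.032 and exact power 0.804. An infeasible design (even
`r = n` fails) returns the sentinel `r = n + 1` with
`feasible = FALSE` rather than an error, so design scans can proceed.

## Survival machinery

Kaplan-Meier curves and the two-sided log-rank (Mantel-Cox) test are
delegated to the survival package (`survfit`, `survdiff`) behind
`km_fit()`/`logrank_test()`; the wrappers pin down conventions the
analyses depend on:

- ties of events and censorings at one time: events first (the standard
  risk-set convention; the data format does not resolve it otherwise);
- the median is the **smallest event time with `S(t) ≤ 0.5`**, boundary
  inclusive. This deliberately differs from `survfit`'s midpoint rule
  when the curve sits exactly at 0.5; a tolerance of `1e-12` guards the
  equality against floating-point drift in the product-limit cumprod;
- degenerate log-rank inputs (no events anywhere, or zero
  hypergeometric variance at every event time) return
  `chi_square = 0, p = 1` with a `degenerate` flag instead of failing.

Both wrappers are tested against independent hand oracles: an explicit
product-limit loop on every event/censor pattern of up to six subjects,
and an explicit observed-minus-expected/variance table for the log-rank
statistic.

## Survival-quartile signature derivation

The core bespoke procedure stratifies a profiled microsatellite-stable
(MSS) subcohort by progression-free survival (PFS) and compares the
extreme quartiles at the mutated-gene level.

**Quartile assignment.** Patients are ranked by observed PFS regardless
of censoring status (the source analysis does not state how censored
times entered; using observed time keeps every profiled patient in the
ranking). Q1 takes the `⌊n/4⌋` shortest, Q4 the `⌊n/4⌋` longest, and the
remainder splits into Q2/Q3 with the extra patient in Q2 — at `n = 49`
this reproduces the 12/13/12/12 split of the motivating cohort. Ties
break deterministically: event before censored, then patient id.

**Derivation.** A gene joins the resistance signature (RES) when at
least one Q1 patient has an alteration of any class (SNV, indel, CNV,
LOH — no VAF or zygosity weighting) in it and no Q4 patient does; the
sensitivity signature (SENS) is the mirror image. A gene altered in both
extremes joins neither, so the two sets are disjoint by construction. A
patient is a carrier (`RES+`/`SENS+`) when they carry at least one
alteration in at least one signature gene.

**Evaluation and the holdout question.** Carriers and non-carriers are
compared by log-rank with per-arm KM medians. Because the signature is
*derived from* the extreme quartiles, evaluating it on the same cohort
is circular, and the package exposes three holdout modes:

- `drop_Q1_positives` / `drop_Q4_positives` reproduce the published
  style of holdout: derivation-quartile patients leave the carrier arm
  only, the non-carrier arm stays intact (the "without the 25th/75th
  percentile" comparisons).
- `drop_extremes` removes both extreme quartiles from *both* arms and
  compares carriers with non-carriers among the middle quartiles only.

The distinction matters. Every Q4 patient is RES− *by construction*
(RES genes have no Q4 alterations), so the intact non-carrier arm
always contains the entire best-prognosis quartile; under a null with
no real gene effects the published-style holdout therefore still
rejects essentially always, and no generator can change that — it is a
property of the set-difference construction, not of the data. The test
suite demonstrates all three behaviours on the simulator: the
derivation-cohort comparison is severely anti-conservative, the
published-style holdout moves the null p upward but keeps the bias, and
`drop_extremes` restores the nominal rejection rate (about 5%). Only
the middle-quartile comparison should be read as a calibrated test;
the other two are descriptive, which is how the stratified medians
should be interpreted.

**TMB and pathway stratification.** Tumor mutational burden is
dichotomized at 10.4 mutations/Mb (the panel-calibrated threshold for
this assay class), boundary inclusive: `TMB ≥ 10.4` is high. Pathway
stratification labels a patient `MUT` on at least one alteration in at
least one pathway gene, compares `MUT`/`WT` PFS by log-rank, and
crosses pathway status with the TMB dichotomy in a 2×2 table under the
two-sided Fisher exact test; degenerate margins return `p = 1`,
flagged.

## Transcriptomics

- **Filtering**: genes with zero counts everywhere are removed, then
  genes below 20 counts. The low-count rule is ambiguous in GUI-driven
  workflows ("< 20 counts" per sample or in total?); both modes are
  implemented, with `total` across samples as the default — at typical
  library sizes a 20-count total is the weaker and safer filter. The
  boundary is strict (`< 20` removed, exactly 20 kept) and the filter
  is idempotent.
- **TMM normalization** via `edgeR::calcNormFactors` (reference sample:
  upper-quartile fraction closest to the mean; two-sided trims 0.30 on
  M and 0.05 on A; inverse-asymptotic-variance weights; factors
  rescaled to geometric mean 1). A degenerate sample with a single
  expressed gene gets factor 1 with a warning, and the remaining
  factors are rescaled among themselves so the overall geometric mean
  stays 1. The suite checks factors against a literal hand-computed
  trimmed weighted mean on small toys.
- **Normalized scale**: `log2(count·10⁶ / (library·factor) + 1)`; all
  downstream t-tests, PCA and template similarities operate on it.
- **PCA**: sample scores of the gene-centered matrix; each component's
  sign is fixed so its largest-magnitude loading is positive, making
  output deterministic across LAPACK builds.
- **Differential expression**: per-gene two-sample Student t-test with
  pooled variance (matching the two-group test of the GUI workflows
  this emulates; Welch available via `var_equal = FALSE`), fold change
  on the linear scale from group means of `2^x` with the
  minus-reciprocal sign convention for down-regulation, selection at
  `|FC| > 2.5` (strict) and unadjusted `p ≤ 0.0128`. The p threshold is
  deliberately the raw working threshold, not an FDR — it reproduces a
  fixed operating point rather than a corrected discovery rule. Genes
  with zero pooled variance get `p = 1` when the means agree and
  `p = 0` when they cannot (deterministic separation).

## Nearest-template-prediction subtyping

Subtype templates are signed marker vectors. `build_templates()` offers
`one_vs_rest` (each class's own ±1 rows) and `pairwise_icms`, the
two-class construction where a gene is a +1 marker of class A only if
it is up in A *and* down in B; concordant genes are excluded and a gene
carrying both signs within one class is an error.

`ntp_classify()` correlates each sample's expression — restricted to
the union of the templates' measured genes and standardized *within the
sample* — against each template's sign vector (zeros on other
templates' genes). Two properties drove the within-sample choice over
the cross-sample gene standardization some classifiers use: the
similarity becomes exactly invariant to affine rescaling of a single
sample's expression (so per-sample scaling artifacts cannot change a
call), and computing over the union keeps single-signed templates
informative as a contrast of one class's markers against the others'.
Pearson correlation is the default; "cosine" differs only in not
centering the sign vector.

Significance uses a permutation null: the sign vector is applied to
seeded random gene subsets of the same size drawn from the measured
gene universe, `p = (1 + #{perm ≥ obs}) / (n_perm + 1)` (floored at
`1/(n_perm+1)` so BH never sees a zero), defaults 1000 permutations.
The best-class p-values are Benjamini-Hochberg adjusted **across
samples** — the unclassified rule is per sample, so samples form the
family — and a sample with `FDR ≥ 0.05` is `UNCLASSIFIED`. One set of
seeded permutation subsets serves every sample, so permuting sample
order permutes the output rows identically. Constant-expression
samples are unclassifiable and produce a warning.

## Over-representation analysis

`ora()` tests each gene set by the one-sided hypergeometric tail
`P(overlap ≥ observed)` after intersecting the set with the universe,
and adjusts across sets by Benjamini-Hochberg (`bh_adjust()`, a
validated wrapper of `p.adjust`). The default universe is the measured
(post-filter) gene list, not the genome: enrichment of a DEG list
should be judged against the genes that could have been selected.

## The synthetic cohort

`simulate_cohort()` exists so every stage is testable without
access-restricted patient data. Its defaults are fixed once, to the
documented structure of the motivating cohort, and are not tuned:

- 55 profiled patients, 6 MSI (so 49 MSS); best responses drawn at the
  observed category proportions (7 CR / 49 PR / 15 SD / 2 NE of 73).
- A 500-gene alteration universe with gamma-distributed per-gene rates
  (shape 0.15, mean 0.0357): a handful of near-ubiquitous driver genes
  plus a long tail of rarely altered ones, giving ~18 alterations per
  patient with classes at the observed SNV/indel/CNV/LOH proportions
  (602:101:258:21). Rate heterogeneity is essential: under a
  homogeneous rate every non-Q4 patient carries some Q1-exclusive gene
  and the non-carrier group degenerates to exactly Q4, which no real
  cohort shows.
- PFS is exponential with baseline median 10.1 months; each carried
  planted gene multiplies the hazard (defaults: five resistance genes
  at HR 4, five sensitivity genes at HR 0.25, 10% marginal carrier
  prevalence — with those hazard ratios carriers concentrate so the
  within-Q1 prevalence is roughly 0.2–0.3). Censoring is the minimum
  of 36-month administrative follow-up and exponential dropout at
  0.01/month. A Weibull shape parameter is available; the default 1
  (exponential) suffices because the analyses consume only ranks,
  medians and log-rank statistics.
- TMB is log-normal with median 6.71 mut/Mb and log-sd 0.85, so the
  cohort straddles the 10.4 cutoff; it is drawn independently of the
  alteration matrix by default.
- The expression layer draws negative-binomial counts (dispersion 0.15)
  for 200 genes: two subtype classes with 25 markers each shifted by
  2 log2 units, and 20 genes shifted by 2 log2 units between the good-
  and poor-prognosis halves of simulated PFS (the planted DEGs).

All draws flow from one integer seed through sub-streams keyed by stage
name, so reconfiguring or disabling one stage never perturbs another's
draws, and identical seeds give field-identical cohorts.

**What passing tests show — and what they do not.** The simulator
produces exchangeable patients, independent gene alterations given the
per-gene rates, exponential hazards and clean NB counts. Real cohorts
have co-mutation structure, copy-number segments spanning many genes,
non-proportional hazards, FFPE-quality expression noise and
batch structure, none of which is modelled. Recovery of planted effects
therefore demonstrates that the *procedures* are implemented correctly
and behave as designed under their assumptions — not that the derived
signatures would validate in an external cohort.

## Problem sizes and numerical conventions

The test suite fixes its own scales: exhaustive survival oracles up to
six subjects; signature-derivation oracles on instances of up to 12
genes; 200 seeded replicates of the 49-patient alteration-only cohort
for the planted-recovery and null-calibration checks; 150–200
permutations and ~70-gene matrices for the NTP checks; exact (not
simulated) coverage computation for the Clopper-Pearson grid. Equality
tolerances are `1e-8`–`1e-12` for deterministic quantities; Monte-Carlo
checks use three binomial standard errors around their targets.
Deterministic tie-breaks are documented at each site (quartile ranking;
PCA sign; TMM reference choice; events-before-censorings).

## Known limitations

- Median confidence intervals (Brookmeyer-Crowley) are not implemented;
  no downstream decision here consumes them.
- Cox models, multivariable adjustment, and stratified or weighted
  log-rank variants are out of scope.
- The NTP permutation scheme is one documented choice among several in
  circulation; published classifier implementations do not fully
  specify theirs, so agreement with any particular external tool is not
  claimed.
- Published subtype sample counts from the restricted expression data
  are not reproducible here; the subtyping is validated on
  template-exact and noise samples with known answers instead.
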