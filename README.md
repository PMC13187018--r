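# trialomics

Translational analysis of single-arm phase II oncology trials with
paired genomic and transcriptomic profiling, for biostatisticians and
translational researchers working on trial cohorts of mCRC-scale size
(tens of patients, targeted-panel DNA, bulk RNA counts).

The package covers, as tested and reusable functions:

- **Exact response statistics.** The A'Hern one-stage design — the
  smallest r with exact binomial tail P(X ≥ r | n, p0) ≤ α — with its
  attained alpha and exact power at an alternative p1, and two-sided
  Clopper-Pearson limits [qbeta(α/2; x, n−x+1), qbeta(1−α/2; x+1, n−x)]
  for every response proportion.
- **Survival stratification.** Kaplan-Meier curves (median = smallest
  event time with S(t) ≤ 0.5, "NR" when never reached) and the
  two-sided log-rank (Mantel-Cox) test, wrapped over the survival
  package with fixed tie and degeneracy conventions.
- **Survival-quartile genomic signatures** — the core procedure. A
  profiled MSS subcohort is ranked by PFS; genes altered in the worst
  quartile (Q1) but in no best-quartile (Q4) patient form a resistance
  signature (RES), the mirror set a sensitivity signature (SENS);
  carriers are compared by log-rank, including held-out variants that
  guard against the circularity of evaluating on the derivation
  quartiles. TMB dichotomization (≥ 10.4 mut/Mb = high) and pathway
  MUT/WT stratification with a Fisher-exact TMB contingency round out
  the genomic layer.
- **Expression analysis.** Low-count filtering, TMM normalization
  (edgeR), log2-CPM, deterministic PCA, and fold-change + pooled-t DEG
  selection (|FC| > 2.5, p ≤ 0.0128).
- **Nearest-template-prediction subtyping** with signed marker
  templates (including the pairwise two-class construction), a seeded
  permutation null, and a Benjamini-Hochberg FDR ≥ 0.05 unclassified
  rule.
- **Over-representation analysis** (hypergeometric tail + BH) against
  user-supplied GMT gene sets.
- **A seeded synthetic-cohort generator** emulating the statistical
  structure such a trial produces — MSS/MSI labels, a skewed sparse
  alteration matrix with per-patient TMB, exponential censored PFS
  with planted resistance/sensitivity hazard ratios, and NB counts
  with subtype and prognosis effects — so the whole pipeline runs and
  is tested without restricted patient data.

See `vignettes/methods.Rmd` for the statistical conventions and design
decisions, and `?run_pipeline` for one-call orchestration
(`inst/scripts/run_pipeline.R` is a thin command-line wrapper).

## Worked example

```r
library(trialomics)

# Exact design and interval for a 73-patient activity trial
ahern_design(73, 0.66, 0.80, alpha = 0.05)
#> A'Hern one-stage design: >= 56 responses of 73 required (p0 = 0.66, p1 = 0.80)
#>   attained one-sided alpha = 0.0324, exact power = 0.8043
clopper_pearson(56, 73)
#> 56/73 = 76.7% (95% CI 65.4 to 85.8)

# Synthetic cohort with planted resistance/sensitivity genes
co <- simulate_cohort(cohort_config(seed = 1))
co
#> Synthetic cohort: 55 patients (6 MSI), 1127 alteration records, 200 x 55 count matrix; seed 1

sig <- signature_analysis(co$clinical, co$alterations)
sig
#> PFS quartiles on 49 patients: Q1 12 / Q2 13 / Q3 12 / Q4 12
#> RES signature: 30 genes; SENS signature: 43 genes
#> RES  : Carrier-stratified PFS (none): + n = 30 (median 3.3) vs - n = 19 (median 28.8)
#>   log-rank p = 9.972e-07
#> RES  w/o Q1: Carrier-stratified PFS (drop_Q1_positives): + n = 18 (median 7.79) vs - n = 19 (median 28.8)
#>   log-rank p = 9.593e-05
#> SENS : Carrier-stratified PFS (none): + n = 36 (median 19.2) vs - n = 13 (median 1.39)
#>   log-rank p = 1.024e-13
#> SENS w/o Q4: Carrier-stratified PFS (drop_Q4_positives): + n = 24 (median 8.02) vs - n = 13 (median 1.39)
#>   log-rank p = 3.322e-09
```

Reading it: the 49 MSS patients split 12/13/12/12 across PFS quartiles;
30 genes are altered in Q1 but never in Q4 (the RES signature) and its
carriers progress much earlier (median 3.3 vs 28.8 months). The
`w/o Q1` line reproduces the published style of holdout (derivation
quartile removed from the carrier arm only). Because that style keeps
every Q4 patient in the non-carrier arm it stays anti-conservative
under a null; a calibrated check excludes both extreme quartiles from
both arms:

```r
evaluate_signature(co$clinical, sig$res_carrier, "drop_extremes", sig$quartiles)
#> Carrier-stratified PFS (drop_extremes): + n = 18 (median 7.79) vs - n = 7 (median 12.2)
#>   log-rank p = 0.9377
```

(Here the planted effect lives almost entirely in the extremes, so the
middle-quartile comparison is rightly unimpressed; the vignette's null
analysis shows why the two readings differ.)

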