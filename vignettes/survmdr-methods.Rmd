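---
title: "Methods: MDR-based SNP interaction analysis for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MDR-based SNP interaction analysis for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survmdr)
```

## The problem

Single-SNP survival association scans miss effects that only exist jointly:
two or three genotypes that together separate patients with different
outcome risk while each marker alone shows nothing. Testing every pair and
triple directly is combinatorially expensive — a 100-SNP panel already
holds `count_combinations(100, 3)` = 161,700 three-way candidates — and the
per-cell data become sparse fast. Multifactor dimensionality reduction
(MDR) addresses both: it collapses the `3^k` joint-genotype table of a
k-SNP combination into one binary high-risk/low-risk attribute and searches
combinations exhaustively under cross-validation.

`survmdr` implements this programme for right-censored survival data and
for a dichotomized (5-year status) outcome, together with the scaffolding a
real analysis needs: genotype QC, covariate adjustment, repeated-run
consensus, permutation significance, main-effect removal, and regression /
Kaplan–Meier validation. A synthetic-cohort generator with planted,
known-truth effects makes every stage testable without access to patient
data.

## Scoring: covariate-adjusted residuals

Cell classification is driven by a per-subject score whose sign says
whether the subject fared better or worse than their clinical covariates
predict.

* **Survival engine (Cox-MDR style).** A covariates-only proportional
  hazards model is fitted by partial likelihood (Breslow ties), and each
  subject receives the martingale residual
  `s_i = delta_i − Lambda0(t_i) exp(gamma' z_i)`,
  the observed minus expected number of events. The Breslow baseline
  `Lambda0` is a right-continuous step function; times beyond its support
  use the right-constant extension.
* **Binary engine (GMDR style).** A covariates-only logistic model of the
  5-year status gives the response residual `s_i = y_i − p_hat_i`. Subjects
  censored alive before the horizon have unknown 5-year status and are
  excluded from this engine entirely.

Both residual types sum to zero by the respective score equations — an
identity the test suite asserts to `1e-8` on every simulated cohort (the
null fits use a convergence tolerance of `1e-12` so the identity holds well
below that bound). Raw residuals are used without standardisation: the
classifier consumes only signs and sums, which standardisation cannot
change.

## The MDR reduction and balanced accuracy

For a candidate combination of k SNPs (k = 1–3), every observed joint
genotype cell receives the sum of its training subjects' scores; cells with
a positive sum are labelled high-risk, cells at or below zero — and cells
never observed in training — are low-risk. The threshold 0 and the
low-by-default rule for empty and exactly-zero cells are deliberate
conservative conventions: absence of evidence never creates a high-risk
call.

Model quality is score-mass balanced accuracy. With `P` the total positive
score mass and `N` the total negative magnitude of the evaluation subjects,

* sensitivity = positive mass captured in high-risk cells / `P`,
* specificity = negative magnitude captured in low-risk cells / `N`,
* BA = (sensitivity + specificity) / 2.

BA is invariant to positive rescaling of the scores, and evaluating a fixed
label map against negated scores maps BA to 1 − BA; both are property
tests. BA is undefined (an error, not a silent value) when the evaluation
scores are one-sided.

## Cross-validated search, selection strategies, consensus

Each run partitions subjects into 5 random folds (sizes differing by at
most one; fold assignment is deterministic under its seed; an
event-stratified mode exists but is off by default since plain random
partitioning is the reference behaviour). Per fold, all `choose(m, k)`
combinations are trained on the 4/5 training scores; the fold-best is the
training-BA maximiser, with exact ties going to the lexicographically
smallest column-index tuple (deterministic and logged), and its testing
balanced accuracy (TBA) is computed on the held-out 1/5.

Two run-level selection strategies are provided because they behave
differently in an important, reproducible way:

* `"tba"` — the fold-best model with the highest mean TBA over the folds
  where it won. Invariant to the column order of the input file.
* `"cvc_first_in_file"` — the model with the highest cross-validation
  consistency (CVC = number of folds won); CVC ties are resolved by the
  earliest input position. This deliberately reproduces the behaviour of
  CVC-based selection in the GMDR lineage: with a tie, reordering the
  input columns changes the answer. The package asserts this
  order-dependence (and the TBA strategy's order-invariance) as a tested
  contract rather than hiding it.

The search is repeated `n_runs = 20` times with independent partitions; the
run-best models are grouped by SNP set and high-risk cell map and the most
frequent group is the consensus ("top") model, frequency ties broken by
mean TBA then CVC. The reported cell map of any selected combination is
retrained on all subjects, so a combination's map is deterministic given
the cohort; consensus grouping therefore effectively keys on the SNP set
with the full-data map attached.

The mean TBA of a run-best model is defined as the mean of its testing BAs
over the folds where it was fold-best. Note that the run-best statistic is
a maximum over candidates, so it sits above 0.5 on pure noise; the
calibrated quantity is the fold-level testing BA of fold-best models, which
the suite checks is centred on 0.5 under the null.

## Permutation testing

Significance of a k-way result is assessed by permuting genotype rows
against the joint (outcome, covariate) rows: all marginals and the
covariate–outcome confounding survive, only genotype association is
destroyed. Because the null-model scores do not involve genotypes, the
score vector is computed once and each permutation only re-links it to the
genotype rows — an exact shortcut asserted equal to naive recomputation.
The fold partition is held fixed, one full search runs per permutation, and
the observed statistic (run-best mean TBA) is computed the same single-run
way for comparability. `p = #(null ≥ observed) / n_perm`, reported as
`< 1/n_perm` when zero; an add-one estimator is available behind a flag but
the default matches the `p < 0.001`-at-1,000-permutations reporting
convention. Calibration is a tested property: under the null the rejection
rate at 0.05 tracks the exchangeability value `(0.05·B + 1)/(B + 1)`.

## The full workflow

1. **QC.** Keep SNPs with MAF ≥ 0.05 (minor-allele relabelling is automatic
   and logged), exact Hardy–Weinberg p > 1e-4 (Levene–Haldane exact test,
   two-sided by probability-mass ordering, no mid-p), and missing-call rate
   ≤ 0 — the screen used for association panels of this kind. Then prune
   statistically redundant markers: within every group of SNPs with
   pairwise r² = 1 only the earliest by input position is kept. r² is
   computed on dosages (composite LD), not phased haplotypes: the data are
   unphased, the measure is deterministic, and at the r² = 1 and r² ≥ 0.8
   decision points the two scales agree for this purpose.
2. **Main-effect removal.** Run the 1-way search; while the permutation p
   stays below alpha (0.05), report the regression validation, then remove
   the top SNP together with every marker at r² ≥ 0.8 with it, and repeat.
   The final non-significant iteration is recorded. Removal is gated on the
   permutation p alone: published workflows of this design proceed past
   regression-non-significant iterations, so regression is reported but not
   a gate (a strict mode requiring both exists behind
   `require_regression = TRUE`; neither mode is claimed to be "the"
   original, which is ambiguous on this point).
3. **Multi-locus search.** 2-way then 3-way on the reduced panel, each with
   permutation testing; significant models are validated by multivariable
   Cox (hazard ratio; low- vs high-risk by default, the convention of the
   survival-engine result tables) or logistic regression (odds ratio;
   high- vs low-risk), with Wald 95% intervals, plus Kaplan–Meier curves
   and the log-rank test. No multiple-testing correction is applied across
   k or across panels — per-test permutation p-values are reported as such,
   and the reports say so.

## The synthetic cohort generator

The generator emulates the data structure of a modest colorectal-cancer
cohort study: n ≈ 400–440 subjects; a panel of common autosomal SNPs (MAF
drawn from \[0.05, 0.5\], Hardy–Weinberg consistent, zero missingness after
QC); block LD; right-censored survival over an ~11-year administrative
window with sparse exponential dropout; and the standard covariates (age at
diagnosis, stage 1–4, MSI status, tumor location, adjuvant chemotherapy,
radiotherapy).

* **Genotypes.** Two independent latent haplotypes per subject; an allele
  is minor when its standard-normal draw falls below the MAF quantile, so
  HWE holds by construction. Within an LD block the latent variables are
  equicorrelated, with the correlation calibrated (via the bivariate normal
  orthant probability) so the dosage r² hits the block target; a target of
  1 produces exact copies. Markers of one block share a target MAF: unequal
  frequencies mathematically cap the attainable r², and tightly linked
  markers have near-identical frequencies in real panels anyway.
* **Survival.** Proportional-hazards Weibull,
  `h(t) = lambda rho t^(rho−1) exp(beta_g 1[cell ∈ high set] + gamma' z)`,
  with covariates mean-centred in the linear predictor. This matches the
  assumptions of the validation analyses and yields known-truth hazard
  ratios for recovery tests. Defaults `lambda = 0.05`, `rho = 1.2`,
  horizon 11 years and dropout 0.03/year give roughly 70% 5-year survival
  and ~55% events over follow-up — a realistic regime for a 1999–2003
  colorectal cohort followed to 2010. Covariate distributions (age
  truncated-Normal(61, 10) on \[20, 75\], stage probabilities
  0.15/0.35/0.35/0.15, binary rates 0.12/0.5/0.55/0.25) are generic
  placeholders exposed in `sim_config()`: the source cohort's exact tables
  are not public, so these are chosen once as plausible values, not fitted.
  Note the truncation means the realised mean age is ≈59.7, the mean of the
  truncated distribution, not 61.
* **Planted effects.** `dominant` and `recessive` single-SNP presets mirror
  the classic 1-way result shape (carrier vs non-carrier cells high-risk).
  The `xor2`/`xor3` presets mark cells with an odd number of heterozygous
  SNPs high-risk: at MAF 0.5 the heterozygote indicator has frequency 1/2,
  so the planted interaction carries *no* marginal dosage–risk correlation
  — the pure-epistasis case the method exists to detect. (A parity over
  carrier indicators would not have this property: carrier frequency at
  MAF 0.5 is 0.75, leaving a marginal correlation of −0.125.)

What the generator does **not** emulate: phased haplotype structure and
recombination maps, population stratification, genotyping error,
informative censoring, X-chromosome markers, and real covariate
distributions. Passing tests therefore demonstrate correctness of the
machinery and its operating characteristics under a clean generative model,
not performance on any particular real cohort.

## Numerical choices

* Breslow tie handling everywhere (null model, baseline, validation fits),
  so the baseline and the residuals are mutually consistent; Efron ties
  would change residuals at tied event times.
* Null-model convergence tolerances `1e-12` (Cox and logistic), so the
  zero-sum score identities hold to `1e-8` with a wide margin.
* Cell threshold `T = 0`; sums exactly at the threshold and unobserved
  cells are low-risk.
* Training-BA ties: lexicographically smallest input-index tuple. On
  continuous scores exact ties occur only when two combinations induce the
  same subject partition; either maximiser is then a correct answer, and
  the brute-force equivalence tests treat it so.
* Duplicate pruning uses r² = 1 within `1e-12`; "keep the earliest input
  position" is a declared convention (the convention used by the source
  workflow is not documented).
* Exact HWE p-values are computed from log-factorials and normalised over
  the heterozygote-count support, so they are stable for any cohort size
  this package targets.
* `count_combinations` uses `choose()`, which is exact for every panel size
  a 3-way scan could ever process.

## Problem sizes used by the test suite

The suite exercises the machinery at deliberately modest scales chosen to
give stable operating characteristics: oracle equivalence on 200 random
instances of up to 50 subjects × 10 SNPs; permutation calibration over 100
null cohorts of 300 subjects × 10 SNPs at 200 permutations; epistasis
recovery and the main-effect workflow over 20 replicates of 600 subjects ×
20 SNPs at 200 permutations; hazard-ratio recovery at n = 2000. The
acceptance script (`scripts/acceptance.R`) recomputes the same quantities
from scratch under a caller-supplied seed. Criteria defined as rates over
20–100 replicates are binomial draws; their stated bands include the
corresponding Monte-Carlo noise, and a borderline draw (e.g. a null
second-iteration false positive in the removal workflow, expected ~5% of
iterations) is within the designed behaviour.

## Known limitations

* k is capped at 3; the enumeration is exhaustive, so very large panels pay
  the full `choose(m, 3)` cost per fold (the scan kernel is compiled, but
  the cost is real).
* The binary engine discards subjects censored before the horizon rather
  than modelling them; this mirrors the dichotomized-outcome design it
  reproduces, and is the reason the survival engine is the primary one.
* Genome-coordinate-aware windowed LD pruning, PLINK binary formats, model
  frailties and time-varying covariates are out of scope.
* Permutation p-values are reported per test; combining evidence across
  interaction orders or panels is intentionally left to the analyst.
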