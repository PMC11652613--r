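---
title: "Heterogeneity quadrants and sampling-bias-aware prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterogeneity quadrants and sampling-bias-aware prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithsig)
```

## The problem

A prognostic gene signature is almost always applied to a single
biopsy, yet a tumor is not molecularly uniform: expression profiles
differ between spatially distinct regions of the same lesion.  When a
signature's genes vary strongly *within* a tumor, the high/low risk
call a patient receives can depend on which region happened to be
sampled.  We call a patient *discordant* under a signature when
different regions of their tumor fall on different sides of the risk
cutoff; a cohort-level discordant fraction above 50% marks the
signature as substantially sampling-biased.

`ithsig` implements a complete pipeline around this idea for
multiregion expression cohorts (several tumor regions per patient,
e.g. multiregion microarray or RNA-seq studies of esophageal squamous
cell carcinoma):

1. score every gene's intratumor and intertumor heterogeneity;
2. partition genes into quadrants and focus on the stable-within /
   variable-between quadrant (Q4);
3. audit any linear risk signature for multiregion sampling bias;
4. build a new signature from Q4 genes via a univariate Cox screen,
   cross-validated lasso refinement, and a multi-learner benchmark
   ranked by Harrell's C-index;
5. evaluate survival models (C-index, Kaplan--Meier/log-rank,
   multivariate Cox, time-dependent AUC, hazard-ratio pooling).

A synthetic-cohort generator with known variance components makes
every stage testable without any external download.

## Heterogeneity scores and their estimands

All expression is assumed log-scale.  For gene $g$ the pipeline
computes two dispersion summaries over tumor samples only:

* **Intratumor score.** For each patient with at least two tumor
  regions, the dispersion metric (SD by default) of the gene across
  that patient's regions; the score is the mean over eligible
  patients.  We deliberately compute dispersion *per patient and then
  average*: pooling all regions of all patients would mix
  between-patient variation into the "within" axis and collapse the
  quadrant logic.
* **Intertumor score.** One tumor region is drawn uniformly at random
  per patient and the metric is computed across patients; this is
  repeated `n_reps = 10` times (regions resampled with replacement
  across repetitions, patients with a single region contributing it
  deterministically) and averaged.  A fixed seed makes the draw
  reproducible, and an exhaustive-enumeration mode replaces the
  sampling on cohorts small enough to enumerate.

Under the additive two-component model
$x_{gpr} = \mu_g + b_{gp} + e_{gpr}$ with
$b_{gp} \sim N(0, \tau_g^2)$ (patient level) and
$e_{gpr} \sim N(0, \sigma_g^2)$ (region level), the intratumor score
estimates $c_4(R)\,\sigma_g$ --- where $c_4$ is the classical
unbiasing constant of the sample SD, available as `c4_constant()` ---
and the intertumor score estimates the SD of the patient-level
mixture, $\approx\sqrt{\tau_g^2 + \sigma_g^2}$.  This second fact
matters: *the intertumor axis does not isolate* $\tau$.  A gene with
large region noise $\sigma$ and negligible patient signal $\tau$
still measures "high inter", because a single random region carries
the region noise with it.  The consequences are discussed under
*Limitations* below.

Three metrics are supported: SD ($n-1$ denominator), MAD (1.4826
consistency constant), and CV (SD/mean).  CV is undefined on values
whose mean is numerically zero --- a real possibility on log-scale
data --- so genes whose relevant mean lies within $10^{-8}$ of zero
get `NA` and are excluded from CV-based analyses.
`metric_agreement()` reports the pairwise Pearson correlations of the
three intratumor scores; high SD--MAD agreement argues that outliers
are not driving the SD.

## The quadrant partition

`assign_quadrants()` thresholds each axis at its arithmetic mean over
all scored genes, giving four quadrants with intertumor on the x-axis
and intratumor on the y-axis: Q1 (low inter, high intra), Q2
(low/low), Q3 (high/high), and Q4 (high inter, low intra).  Q4 genes
are the candidate pool for signature building: stable within a tumor
(small sampling bias) yet variable between patients (discriminative).
Scores exactly at a threshold count as "high" on both axes --- a
deterministic tie-break that only matters on measure-zero boundaries
of real data but makes degenerate inputs (all genes identical) land
in a single well-defined quadrant (Q3).

Before scoring, genes with zero variance across tumor samples are
dropped (they carry no information on either axis); an optional
mean-expression quantile filter is provided but off by default, since
any particular "expressed gene" universe is a study-specific choice
that should be made explicitly.

`quadrant_enrichment()` compares the quadrant composition of a query
gene set (e.g. the union of previously published signature genes)
against the universe shares and reports observed/expected folds.

## The sampling-bias audit

A signature is a named list of (gene, coefficient) pairs; the risk
score of a sample is the linear predictor
$\sum_i c_i \, x_{i}$ (`risk_score()`).  Signature genes missing from
a matrix are dropped and reported, never zero-imputed: on log-scale
data zero is an actual expression value, and silent imputation would
shift every score by an arbitrary constant.

`stratify()` cuts scores at the cohort median (mean of the central
pair for even counts); *high* requires a score strictly above the
cutoff, so ties are classed low and an even cohort splits exactly in
half.  The multiregion audit (`region_concordance()`) scores every
tumor region, takes the median over all tumor region samples as the
cutoff --- the only cohort statistic the per-region protocol defines
--- and labels each patient concordant-low, concordant-high, or
discordant from the set of their regions' classes.  The cohort is
flagged biased when the discordant fraction exceeds 0.5.  Two
companion statistics complete the audit: `risk_dispersion()` (mean
per-patient SD of region scores; how far a single biopsy can move a
patient) and `score_variance()` (cohort-level score variance; how
much between-patient signal the signature retains).

## The selection pipeline

* **Univariate screen** (`univariate_cox()`): one Cox fit per gene
  (Efron ties, via the survival package), Wald p-values, selection at
  `p < 0.05` with *no* multiplicity correction --- the screen is a
  coarse pre-filter whose per-gene type-I rate is the controlled
  quantity; the penalized step downstream handles redundancy.
  Multiregion cohorts are first reduced to one value per patient by
  region averaging (`aggregate_by_patient()`): survival is a patient
  attribute, and regions are exchangeable draws around the patient
  mean.
* **Lasso refinement** (`lasso_refine()`): L1-penalized Cox over a
  100-point lambda path (glmnet), with lambda chosen to maximize the
  mean 5-fold cross-validated Harrell C-index.  Fold assignment is a
  pure function of (k, seed, n), so runs are reproducible.
* **Benchmark** (`benchmark_select()`): every available learner is
  fitted on the candidate genes and ranked by the unweighted mean of
  (a) the mean held-out C-index over 5 CV folds of the training
  cohort and (b) the C-index of the train-fitted model applied,
  without refitting, to each external validation cohort.  The
  unweighted mean is the simplest reading of "average C-index across
  datasets" and is isolated in one place so alternatives are a
  one-line change.  Ties break toward fewer selected genes, then
  lexicographic name.  Expression is standardized per gene within
  each cohort independently before fitting or scoring --- the
  cross-platform convention --- so exported coefficients live on the
  standardized scale.

The learner registry ships StepCox (forward / backward / both,
AIC criterion), ridge (`alpha = 0`), elastic net (`alpha` grid
0.1--0.9), lasso with CV-selected penalty, random survival forest
(ranger, `num.trees = 1000`), and a Cox-objective gradient boosting
machine (xgboost, 10000 trees, depth 3, shrinkage 0.001, minimum
node size 10).  `CoxBoost`, `plsRcox`, `SuperPC`, and `SurvivalSVM`
are registered but marked unavailable --- no supported implementation
backs them here --- and requesting one errors with the list of
learners that actually run: the registry keeps the benchmark honest
about its coverage.  Every learner's output is orientation-normalized
(training C-index at least 0.5, flipping the sign if needed) so that
a higher score always means higher predicted hazard.

## Evaluation utilities

* `harrell_cindex()`: Harrell's conventions exactly --- a pair is
  comparable when the earlier time is an observed event (or times tie
  with exactly one event), tied scores count 0.5, pairs tied on time
  with two events are not comparable.  The implementation is
  cross-checked in the test suite against both an O(n^2) enumeration
  oracle and `survival::concordance()`.
* `km_logrank()`: product-limit curves per class and the two-group
  log-rank test (survival package); a group with zero events keeps
  the statistic defined and warns.
* `multivariate_cox()`: joint Cox fit with an explicit rank check
  that names collinear columns, plus an events-per-covariate warning.
* `time_dependent_auc()`: cumulative-case / dynamic-control AUC with
  inverse-probability-of-censoring weights from the Kaplan--Meier
  estimate of the censoring distribution (left limits at case times).
  With no censoring before the horizon it reduces to the empirical
  case/control AUC, which is the oracle used in its tests.
* `pool_hr()`: fixed-effect inverse-variance pooling with Cochran's
  Q, $I^2 = \max(0, (Q - \mathrm{df})/Q)$, and the chi-squared
  heterogeneity p-value.  Fixed-effect is the default because the
  target use is pooling one model's hazard ratio across a small
  number of cohorts; a random-effects variant was considered and left
  out of scope to keep a single well-tested estimator.

## The synthetic generator

`generate_cohort()` draws from exactly the two-component model the
scores estimate, organized in archetype blocks mirroring the
quadrants (Q1-like: high $\sigma$, low $\tau$; Q2-like: both low;
Q3-like: both high; Q4-like: high $\tau$, low $\sigma$).  Survival is
exponential proportional hazards with linear predictor
$\sum_j \beta_j(\mu_j + b_{jp})$ over planted Q4-like genes ---
patient-level signal only, never region noise, encoding the premise
that prognosis is a patient attribute while region sampling adds
nuisance variation.  An exponential baseline keeps censoring
calibration analytic: given patient hazards $h_p$, independent
exponential censoring at rate $c$ censors patient $p$ with
probability $c/(c+h_p)$, and $c$ is solved numerically so the
expected censored fraction matches `censor_rate`.  (The baseline
shape is immaterial to the downstream rank-based methods, which are
all semiparametric; a Weibull baseline would be a straightforward
extension.)

Defaults --- chosen once as a realistic mid-size multiregion study
and used as the standing test conditions --- are 100 patients with 3
regions, four 250-gene blocks with SD levels 0.2/1.0 on a mean
log-expression of 7, a 10-gene planted signature with
alternating-sign effects of magnitude 0.6 per expression unit
(hazard ratio 1.8 per unit, the strength of a usable signature
gene), baseline hazard $\log 2/900$ per day (900-day median
survival), and 30% expected censoring, typical of an aggressive
carcinoma cohort with mature follow-up.  A single seed drives
generation through fixed per-stage sub-seeds (patient effects, region
noise, event times, censoring times), so changing the censoring
target does not alter the expression draw.

What the generator does *not* emulate: count/library-size effects,
batch effects, platform differences, copy-number-driven expression,
spatial coordinates, or non-proportional hazards.  Green tests on
synthetic data therefore demonstrate the estimators' correctness
under the stated model, not robustness to those real-data
complications.

## Numerical and design choices

* SD everywhere uses the $n-1$ denominator; the variance-component
  tests correct the expected SD by `c4_constant(n)`.
* Intertumor repetitions resample regions with replacement across
  repetitions (each repetition independent), matching a plain
  "repeat 10 times" protocol with no stated exclusion.
* Delimiters are chosen by file extension only (`.csv` comma,
  otherwise tab); no content sniffing, so parsing is deterministic.
* Expression is assumed log-scale; `read_cohort(log1p = TRUE)`
  applies `log2(x+1)` for linear-scale (TPM) inputs and records the
  transform on the returned object.
* Probe-to-gene collapsing (`collapse_probes()`) keeps the probe with
  the highest mean expression per gene --- the common convention;
  the rule is a documented choice, not a recovered fact.
* Degenerate inputs are first-class: constant genes are flagged (Cox
  screen) or contribute zero dispersion; all-identical risk scores
  stratify to all-low with a warning; a lasso path retaining no gene
  at any lambda is a hard error rather than an empty signature.

## Problem sizes used in the shipped tests

The test-suite simulations are sized for a single CPU: cohorts of
100--500 patients, gene universes of 200--2000, 20-seed replications
for the paired bias comparisons, and a 300+150+150-patient
train/validation benchmark over the full learner registry.  These
sizes give the quoted tolerances (e.g. 10% relative error on
variance-component recovery at 500 patients) comfortable margins
under the fixed seeds.

## Limitations

* The intertumor estimator's estimand is $\sqrt{\tau^2+\sigma^2}$,
  so genes with large region-level noise and little patient-level
  signal (Q1-like) are pushed toward the high-inter side and
  systematically land in Q3 when their total dispersion exceeds the
  cohort-mean threshold; with strongly separated components a
  fraction of Q4-like genes likewise falls below it.  Quadrant
  recovery is therefore reliable only when $\sigma_{\text{high}}$
  stays below the between-patient SD scale of the cohort --- the
  regime the recovery tests use --- and Q1/Q4 boundaries should be
  read with this confound in mind on real data.  Subtracting a
  within-patient variance estimate from the intertumor axis would
  remove the confound but would depart from the established
  random-region protocol this package implements.
* The audit's median cutoff is recomputed per cohort; transferring a
  cutoff across cohorts is supported (`cutoff =`) but the default
  mirrors the per-cohort protocol.
* External validation applies train-fitted coefficients directly
  (after per-cohort standardization); per-cohort refitting is out of
  scope.
* The benchmark's non-linear winners (RSF, GBM) cannot be exported
  as a (gene, coefficient) signature; the fitted scoring closure is
  returned instead and flagged as such.
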