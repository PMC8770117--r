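---
title: "Methods: cfRNA pregnancy progression and pre-eclampsia risk"
author: "cfRNAprog authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfRNA pregnancy progression and pre-eclampsia risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfRNAprog)
library(SummarizedExperiment)
```

# Scope and model

Plasma cell-free RNA (cfRNA) is a mixture of transcripts shed by maternal,
placental and fetal tissues. Sampled across gestation, its composition
changes smoothly enough that a single blood draw carries a readable clock of
pregnancy progression, and deviations from the normative trajectory flag
placental pathology — most importantly pre-eclampsia — months before
clinical presentation. `cfRNAprog` implements that analysis chain for
gene × sample count matrices collected across multiple cohorts:

1. **Synthetic multi-cohort generator** with complete ground truth, so
   every downstream stage can be validated by parameter recovery without
   access-controlled patient data.
2. **Depth and cohort correction** of log2(CPM+1) expression with a strict
   no-leakage train/apply contract.
3. **Gestational-age (GA) clock**: lasso regression with 10-fold CV, MAE
   loss, one-standard-error penalty selection, learning curves and a
   sequential ANOVA variance decomposition over clinical covariates.
4. **Gene-set partitioning trends**: cumulative-CPM scores, per-week slope
   regression with BH control, permutation scrambling, multi-cohort
   confirmation and an exact 1/24-null monotonicity test over four ordered
   draws.
5. **Pre-eclampsia (PE) classifier**: leave-one-out CV with fold-internal
   Spearman screening, unpenalised logistic regression, bootstrap CIs,
   PPV arithmetic, delivery-timing survival comparison and
   specificity/robustness side analyses.

# The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. Its defaults
*are* the study conditions the rest of the package is validated under.

**Count model.** Gene `g` in sample `s` has log2 relative abundance

```
x[g,s] = baseline[g] + slope[g] * GA[s] + offset[g, cohort(s)]
         + panelEffect[g] * I(case(s))
```

Relative abundances `2^x` are normalised per sample and scaled by a
lognormal library size; counts are negative-binomial with fixed dispersion
(variance `mu + phi * mu^2`). This is the standard overdispersed RNA count
model; because CPM normalisation is compositional, the realised log2-CPM
equals `x` up to a per-sample constant that is effectively shared across
cohorts once a few thousand genes average out the normalisation factor.

**Defaults and why.**

* 8 cohorts × 150 samples, 2,000 genes — a desk scale that exercises every
  code path; the full ~13,000-gene, ~2,400-sample scale adds nothing to
  validation.
* Per-cohort GA windows follow the reference eight-cohort design (each
  cohort samples a distinct but overlapping span of 4.9–40.2 weeks), so
  cohort effects are *partially confounded* with gestational age — exactly
  the confound the correction must untangle.
* `trend_frac = 0.1`, `slope_scale = 0.05` log2-CPM/week: a sparse minority
  of genes trend, with per-week changes that accumulate to ~1–1.5 log2
  units across gestation, in line with moderate placental transcript
  dynamics.
* `cohort_offset_sd = 0.5` log2-CPM: batch shifts comparable to the trend
  signal itself, a deliberately hard setting.
* Library sizes lognormal(log 3e6, 0.4), NB dispersion 0.2 — typical for
  low-input plasma RNA sequencing.
* `pe_prevalence = 0.137` and a 7-gene coding panel match the reference
  case–control design; `pe_effect = 1.0` log2 units (a twofold shift with
  random sign per gene) reflects the several-fold perturbations reported
  for placental PE markers such as PAPPA2.
* Gene sets (20 sets, 10–50 genes) are sampled so 60% of a trending set's
  members share the intended slope sign — their aggregate direction is
  known a priori and recorded in the truth object.
* Clinical covariates (BMI, age, race) are generated independent of
  expression by default, matching the finding that they explain under 1%
  of model variance; a `confounded_covariates` stress mode ties BMI to GA.
* Delivery GA is `40 − Exponential` weeks truncated to [24, 42], shifted
  ~3 weeks earlier for PE cases, supporting the Kaplan–Meier stage.

**What it does not emulate.** Read-level artefacts (fragment length,
capture bias), subject-level random intercepts, population structure in the
race covariate, and gene–gene correlation beyond shared GA trends. Passing
parameter-recovery tests on this generator therefore shows the algorithms
are correct and calibrated, not that real plasma data meet their
assumptions.

# Correction with a no-leakage contract

All corrections are fitted in log2(CPM+1) space (the one space the
modelling appendix names; adopted globally for coherence). Depth correction
precedes cohort correction.

1. **Depth**: per gene, a simple linear fit of expression on per-sample
   total counts; the correction is the residual plus the gene's training
   mean (re-added so corrected values stay on the log2-CPM scale and
   CPM-space partition scores remain meaningful downstream).
2. **Cohort**: per gene, expression is residualised on the variable of
   interest (GA) *within training*; cohort offsets are the cohort means of
   those residuals. Only the cohort effect orthogonal to GA is corrected —
   a cohort that merely samples late pregnancy is not "corrected" into
   looking early.
3. **Apply**: subtract stored depth fit and offsets. The signature of
   `applyCorrection()` has no GA argument, so held-out covariates cannot
   leak by construction; a test permutes held-out GA and asserts
   byte-identical output.

Cohorts with fewer than two training samples get offset 0 with a warning;
unseen cohorts at apply time are depth-corrected only. Offsets are simple
residual means (a one-way fit on residuals) rather than a joint model —
the simplest estimator consistent with the three-step algorithm, and the
one whose recovery we can verify to ±20% at 200+ samples per cohort.

QC outliers are flagged before any fit: any monitored metric (default
total reads, duplication rate, ACTB Ct) more than 3 s.d. from its mean
flags the sample.

# The gestational-age clock

* Features: protein-coding genes with median expression above zero in
  training. (The positive-median rule is the retention criterion; at the
  reference scale it leaves ~13,000 genes, here ~70% of simulated genes.)
* Split: stratified by GA into 8 equal-width bins over the observed range
  (the stratum definition is otherwise unspecified; equal-width bins keep
  the rule data-independent), default 80/20.
* `cv.glmnet` with `type.measure = "mae"`, 10 folds, a 100-point
  auto-scaled log-spaced penalty grid, features centred/scaled on training
  statistics. Errors are reported in days (weeks × 7).
* Penalty: the largest penalty within one SE of the CV minimum,
  implemented in `selectOneSE()` and verified against an exhaustive
  grid-scan oracle on 1,000 random curves.
* `refitTopK()` ranks nonzero coefficients by absolute standardised weight
  and retrains the lasso (same CV/one-SE procedure) on the top k = 50.
* ANOVA is sequential (type-I) with the cfRNA prediction entered first —
  the decomposition that matches the claim "driven almost entirely by the
  transcripts"; term order is an argument for sensitivity analysis. Race
  enters as unordered indicators with the most frequent level as
  reference. When covariates are orthogonal to the prediction the first
  fraction equals the squared prediction–truth correlation (tested).
* `compareModels()` is a paired bootstrap (B = 1,000) over per-sample
  absolute errors for judging whether adding covariates moves MAE.

# Gene-set partitioning and monotonicity

Cumulative CPM — the sum of member-gene CPM per sample — measures a set's
share of the plasma transcriptome; a partition of the gene universe sums
to 1e6 per sample (tested). Per (set, cohort), scores are regressed on GA
in weeks; slopes are in CPM/week and scale linearly with the data (tested).
Discovery uses BH-adjusted p < 0.01 across sets within the discovery
cohort; confirmation requires unadjusted p < 0.05 *with matching slope
sign* in at least two other longitudinal cohorts, and the number of
significant cohorts including discovery is reported. Sign matching is the
natural reading of "confirmed"; significance with the opposite sign is
counted as non-confirming.

The monotonicity test classifies each subject's four draw-ordered scores
as strictly increasing, strictly decreasing, or neither. Strictness is the
chosen definition: continuous scores make ties measure-zero, and it is the
definition under which exactly 1 of the 24 draw orderings is monotone-up
(and 1 monotone-down), giving the analytic 1/24 null. Ties are counted
non-monotone and logged. The observed monotone count per direction is
tested against Binomial(n, 1/24) with a one-df chi-squared goodness-of-fit
(direction tested separately, complement pooled); because "a chi-squared
test" does not pin down the df convention, an exact binomial p-value is
reported alongside. `enumerateDrawOrderings()` exposes the combinatorial
null explicitly.

# Pre-eclampsia classification

Inside every leave-one-out fold: a two-sided Spearman screen (average
ranks, t-approximation p-values, BH across all genes within the fold)
retains genes at adjusted p < 0.05; an unpenalised logistic regression on
the retained genes (standardised on fold-training statistics) yields the
held-out probability. Consensus features are the intersection across
folds. Cohort correction is applied before modelling with GA at collection
as the variable of interest — GA, not outcome, is the "as before" variable,
and the correction consumes no labels.

Folds whose screen retains nothing emit a fold-independent probability of
0.5. This is a deliberate numerical choice: emitting the fold-training
prevalence instead would anti-correlate with the held-out label across
LOOCV folds (held-out case ⇒ slightly lower training prevalence) and bias
null AUC far below 0.5; the uninformative constant keeps shuffled-label
AUC at chance, which the null-calibration tests verify.

AUC is the normalised Mann–Whitney statistic (ties count one half),
verified against exhaustive pair enumeration. The operating threshold is
the largest one achieving 75% sensitivity on out-of-fold probabilities;
PPV follows the closed formula
`sens·prev / (sens·prev + (1−spec)(1−prev))`, which is algebraically
identical to TP/(TP+FP) when all three inputs are measured on the same
sample (tested on random confusion matrices). CIs are percentile intervals
from B = 1,000 class-stratified bootstrap resamples. The k-fold learning
curve (k = 2…9 plus LOOCV) reuses the identical fold pipeline. Delivery
timing is compared by Kaplan–Meier curves and a log-rank test without
censoring (all deliveries observed; a censoring argument exists for
generality), optionally excluding spontaneous preterm deliveries.
Subtype specificity screens chronic- and gestational-hypertension controls
against normotensive controls at raw p < 0.05 (the threshold used for
that side analysis) and reports overlap with the PE gene list.

# Numerical choices and degenerate inputs

* All-zero samples abort CPM conversion with the sample named; all-zero
  genes get zero offsets and zero coefficients without special-casing.
* Zero-variance QC metrics are skipped with a warning; zero-variance genes
  are skipped by the Spearman screen with a log message.
* Strata of size one go to training with a warning; strata of size ≥ 2
  contribute at least one sample to each side, and the per-stratum test
  count is the rounded global fraction.
* The lasso solver needs two columns, so single-feature refits are padded
  with an all-zero column that is dropped from the returned model.
* Permutation p-values use the add-one correction, bounded below by
  1/(n_perm+1).
* Bootstrap resamples are stratified by class, so one-class resamples
  cannot occur.
* Seeds: every stochastic step takes an explicit seed; `runPipeline()`
  expands one global seed into per-stage seeds by fixed offsets.

# Problem sizes

Tests and the acceptance script run at deliberately reduced scale chosen
once as this package's validation conditions: parameter-recovery suites
use 2–4 cohorts of 60–260 samples and 200–600 genes; the panel-recovery
sweep uses 20 seeds of 150-sample case–control designs; null calibration
uses 2,000 monotonicity simulations and 40 shuffled-label LOOCV runs; the
end-to-end acceptance run uses the generator's 8 × 150 × 2,000 defaults.
These sizes exercise every code path with adequate statistical power while
keeping a full validation run in minutes on one CPU.

# Known limitations

* The correction is linear throughout; nonlinear (spline) depth or cohort
  effects and flowcell-level batch structure are out of scope.
* The generator's independence assumptions (genes conditionally
  independent given GA, covariates independent of expression) make the
  recovery tests necessary but not sufficient evidence for real-data
  performance.
* Whether "standardising cohort means" in the headline description is
  exactly the three-step orthogonal correction is assumed, not stated, by
  the source description of the method; the three-step algorithm is what
  is implemented.
* The final all-data clock refit reuses the previously selected penalty
  rather than reselecting it; depth correction is refit per training
  split.
* PE learning-curve AUCs at small k are noisy at desk scale; the LOOCV
  terminal point is the headline metric.
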