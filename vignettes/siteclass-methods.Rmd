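---
title: "Site-aware classification of multi-site ROI tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-aware classification of multi-site ROI tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteclass)
```

## The problem

Consortium neuroimaging studies pool FreeSurfer-style regional measures
(cortical thickness, surface area, subcortical and ventricular volumes,
intracranial volume) from dozens of scanning sites to ask whether a
case--control diagnosis such as obsessive-compulsive disorder can be decoded
at the individual-subject level. Three methodological hazards dominate such
analyses, and this package exists to make each one measurable:

1. **Site effects.** Every site contributes a systematic shift and rescaling
   of the features (scanner, protocol, sample composition). A classifier can
   exploit site identity — directly through covariates, or indirectly through
   the brain data — whenever class membership is unevenly distributed over
   sites.
2. **Validation design.** Internal k-fold cross-validation that stratifies
   folds by site answers a different question than leave-one-site-out (LOSO)
   validation, which simulates deployment at an unseen site. The gap between
   them, and the dispersion of fold scores, quantifies between-site
   heterogeneity.
3. **Clinical heterogeneity.** Patient subgroups (medication status, symptom
   severity, onset age, illness duration) can be far more separable than the
   case--control contrast itself, and correlated clinical variables can
   masquerade as one another.

The real consortium data such analyses run on are private. The package
therefore ships a synthetic cohort generator whose parameters control exactly
the properties the pipeline claims to measure, so every stage is testable
end to end with known ground truth.

## The pipeline

For one analysis (a cross-validation scheme, a classifier, a covariate
regime, optionally a clinical contrast), `run_pipeline()` executes:

1. **Global missingness exclusion.** Subjects with strictly more than 10% of
   feature cells missing are removed once, before any split
   (`exclude_high_missingness()`).
2. **Fold construction** (`cv_engine`): one of
   - *site-stratified k-fold* (default k = 10): fold sizes differ by at most
     one subject globally and by at most one subject within every
     site-by-diagnosis cell;
   - *LOSO*: each site is once an intact external test set;
   - *size-matched stratified folds*: as many folds as sites, with the test
     sizes forced to equal the LOSO test-size multiset but membership mixed
     across sites — this isolates the variance contribution of unequal fold
     sizes from that of between-site heterogeneity;
   - *repeated stratified k-fold* (default 5 folds, 10 repeats) for
     single-site analyses.
3. **In-fold preprocessing.** Per-feature medians and interquartile ranges
   are estimated on training rows only (quartiles by linear interpolation);
   missing cells are imputed with the training median; features are centred
   on the training median and divided by the training IQR (divisor 1 when
   the IQR is 0). Categorical covariates are one-hot encoded against the
   training level inventory; unseen levels encode as all-zero rows.
4. **Covariate regime.** `brain_plus_covariates` concatenates the scaled
   brain block with age and the full (no reference drop) sex and site
   indicators; `brain_only` and `covariates_only` use one block each;
   `residualized_brain` regresses every feature on an intercept, age, and
   reference-dropped sex/site indicators by QR least squares, with
   coefficients estimated on training rows and subtracted from both sides of
   the split.
5. **Model fitting** with optional PCA and nested tuning (below).
6. **Evaluation.** Per-fold AUC (skipped with a logged count when a LOSO
   test site contains a single class), balanced accuracy, sensitivity and
   specificity; pooled AUC over per-subject test scores; Mann--Whitney
   significance; Hanley--McNeil 95% interval; Bonferroni flag at
   `alpha / n_comparisons` (default 0.05/30, i.e. three CV designs by ten
   classifiers).

All randomness derives from one seed expanded into per-stage streams by a
documented hash (`derive_seed()`), so identical inputs give bit-identical
serialized reports.

## The classifier zoo

Eleven configurations behind one `fit_model()`/`predict_scores()` contract:
linear and RBF support-vector machines (with and without PCA), L1 and L2
logistic regression, PCA + logistic regression, a linear-kernel
Gaussian-process classifier, a random forest, gradient-boosted trees, and a
fully connected neural network with hidden layers of 60, 40 and 20 units.
PCA, when requested, is fit on training rows and keeps the minimal number of
leading components explaining at least 90% of the variance.

Tuning is enabled for the SVMs, logistic regression and the boosted trees:
an inner stratified cross-validation (default 5 folds) scores every grid row
by mean inner AUC and refits the winner on all training rows; ties go to the
earlier grid row. The grids are conventional log-spaced defaults, declared in
`default_tuning_grid()`: SVM cost {0.01, 0.1, 1, 10}; RBF gamma as the
`1/(p Var(X))` heuristic times {0.1, 1, 10}; logistic penalty
{0.01, 0.1, 1, 10}; boosted-tree depth {2, 4, 6} by learning rate
{0.05, 0.1, 0.3} at 200 rounds. The forest is fixed at 500 trees with
`sqrt(p)` candidate features per split and the Gaussian process runs at the
default linear-kernel settings, both following standard recommendations
rather than tuning. The network trains full-batch with Adam, class-balanced
cross-entropy, a 10% stratified validation split and early stopping
(patience 15, cap 200 epochs).

Scores are class probabilities for the forest, boosted trees, Gaussian
process and network (hard-label threshold 0.5 for secondary metrics) and
margins for the SVMs and logistic regression (threshold 0).

## Statistical inference for the AUC

The AUC is computed by the mid-rank Mann--Whitney identity: the probability
that a random case outscores a random control, ties counted half, so
`U = AUC * n1 * n0` exactly. Significance is two-sided. For
`n1 + n0 <= 12` the null is enumerated exhaustively over all label
assignments of the observed scores (ties handled by construction); above
that, a normal approximation with tie-corrected variance and a 0.5
continuity correction is used, which matches the classical corrected
rank-sum test. For tie-free scores the two routes agree within 0.02 at the
enumeration boundary; with heavy ties at such small n the normal
approximation degrades, which is precisely why the exact path is the default
there. The 95% interval uses the Hanley--McNeil variance with normal
quantiles, truncated to [0, 1].

Pooling choice: significance is computed on the per-subject test scores
concatenated across folds (averaged across repeats in the repeated scheme),
giving a single well-defined U per analysis; fold-wise AUCs are reported
alongside for dispersion. Fold-level testing remains available by applying
`mwu_auc_inference()` to fold scores directly.

## Permutation feature importance

For the forest only, and only on residualized brain features — covariate
columns never enter the importance analysis, so importances are
interpretable as imaging contributions. Observed importance is the impurity
importance on the true labels; the null distribution comes from `B` refits
on label-permuted responses (response permutation, not per-column shuffles:
the null of interest is "no outcome association", and one refit per
permutation prices in the forest's ability to overfit noise). The p-value
`(1 + #{null >= observed}) / (B + 1)` has floor `1/(B+1)` and is never zero.
Selection is per-fold Benjamini--Hochberg, then a feature is *consistent*
when selected in strictly more than half the folds.

A structural constraint worth knowing: with `k` informative features among
`m`, BH selection at level `q` is impossible unless
`1/(B+1) <= q * k / m`. At `B = 200`, `m = 157` and `k = 10` this rules out
`q = 0.05` entirely (floor 0.0050 > 0.0032); the package default is
`q = 0.05` for generic use, and the end-to-end validation of the importance
machinery runs at `q = 0.10`, where the floor clears the entry threshold and
the realized false-discovery proportion is checked against 0.10.

## The synthetic cohort generator

`generate_cohort()` draws, under one seed: log-uniform site sizes (skewed,
as consortium site sizes are); per-site, per-feature additive offsets
(SD `site_offset_sd`) and lognormal multiplicative factors
(`site_scale_sd`); per-subject age and sex with small per-feature loadings;
a diagnosis effect (d in within-site SD units added to cases on a random
feature subset); a medication effect added to medicated cases on its own
subset; and unit Gaussian noise. Medication status is assigned with a
configurable fraction of *pure* sites (all cases medicated or none), the
lever behind the site-confounding experiments. Illness duration is drawn
from two Gaussians whose mean gap is solved in closed form from the target
point-biserial correlation with medication status (default r = -0.094,
realized within ±0.05 for cohorts of 2000+ subjects); onset age is age minus
duration; severity scores are truncated rounded Gaussians. Missingness is
applied last: a heavy subset (default 5% of subjects) is forced above the
10% exclusion threshold and the rest of the cells are masked i.i.d.

Defaults mirror the consortium geometry the framework targets: 46 sites,
sizes 20--250 (log-uniform mean near 90), 53% cases, 157 features (2 x 34
Desikan-Killiany thickness + surface-area parcels, whole-hemisphere
measures, 2 x 7 subcortical volumes, two lateral ventricles, ICV), with
FreeSurfer-style feature names so schema code is exercised realistically.
Site offset/scale SDs (0.4 / 0.1) are free parameters — no public estimates
of consortium scanner dispersion exist — chosen to make site identity
decodable from features well above chance without drowning the
condition effects.

What the generator does **not** emulate: inter-regional covariance (features
are independent given the structural terms), non-Gaussian tails, informative
(non-MCAR) missingness, age-by-diagnosis interactions, and site-specific
class-definition drift. Passing tests therefore demonstrate that the
*pipeline machinery* behaves correctly under the stated statistical
structure, not that any particular real dataset is classifiable.

## Numerical and design choices

- Quartiles by linear interpolation between order statistics (R type 7);
  IQR 0 falls back to divisor 1.
- One-hot blocks keep all levels for the models (conventional for trees and
  kernels); the residualizer uses its own intercept + reference-dropped
  design to stay full rank, and errors naming the offending columns when the
  design is collinear anyway.
- Under LOSO the held-out site is unseen by the residualizer and its
  indicator contributes zero, i.e. the site is treated as the reference
  level — the only coherent choice for an unseen level.
- Residualization is applied after robust scaling and before model fitting.
- Fold assignment shuffles subjects only after a stable sort by subject id,
  so plans are reproducible across platforms; remainders go to the folds
  with the smallest current totals, keeping global fold sizes within one.
- Single-class LOSO test folds: accuracy-type metrics are not computable
  meaningfully and AUC is undefined, so the fold is skipped for AUC with a
  logged count and excluded from pooling.
- Contrast thresholds are closed/open exactly as printed in the clinical
  conventions: severity low when YBOCS <= 24; onset early when < 18 years;
  duration short when <= 7 years. Patients missing a stratification
  variable are excluded from that contrast only.
- Intersected sensitivity reruns skip cells below 50 subjects per class (CIs
  below that are uninformative); the floor is configurable.

## Problem sizes used in the shipped validation

The test suite and the acceptance script run everything at desk scale,
chosen once: null and signal-recovery cohorts of 600 subjects across 6
sites; a confounded cohort of ~650 subjects across 12 sites
(`site_offset_sd = 1.0`, 80% medication-pure sites, medication d = 0.4);
a 2000-subject cohort for the sensitivity-rerun stability check
(medication d = 0.8, duration carrying no feature effect); importance
validation on 250 subjects with 10 informative features (d = 1.0) among
157, B = 200 permutations, 100 trees per refit, 10 folds, five seeds.
Forests elsewhere use the fixed 500 trees.

## Known limitations

- The generator's independence assumptions make classification *easier* per
  unit effect size than correlated real features would; absolute AUCs on
  synthetic cohorts are not predictions for real data.
- The Gaussian-process classifier is O(n^3) in training subjects and is
  practical here only for cohorts of a few thousand.
- Probability calibration is out of scope; scores are used only through
  ranks and fixed thresholds.
- No site-harmonization (e.g. empirical-Bayes batch adjustment) is provided;
  the residualization regime is deliberately the plain train-fitted linear
  correction whose behaviour the framework quantifies.

## A worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_config(n_sites = 12,
                                    site_size_range = c(25, 100),
                                    site_offset_sd = 1.0,
                                    site_medication_purity = 0.8,
                                    medication_effect = c(40, 0.4),
                                    seed = 501))
contrasts <- build_contrasts(co$table)
cfg <- run_config(feature_regime = "covariates_only",
                  subgroup_contrast = contrasts$medicated_vs_unmedicated,
                  model_specs = model_spec("rfc", seed = 2), seed = 2)
report <- run_pipeline(cfg, co$table)[[1]]
report
```

With these settings the covariates alone (age, sex, site) classify
medication status nearly perfectly — the site-confounding signature — while
rerunning with `feature_regime = "residualized_brain"` collapses the AUC
toward chance, because with 80% medication-pure sites the between-site
variance that residualization removes *is* most of the medication signal.
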