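---
title: "Classifying subject groups from atlas-based voxel counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying subject groups from atlas-based voxel counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roiclassify)
```

## The problem

Task fMRI contrasts yield, for each subject, a 3-D map of t-statistics: one
value per 2 mm voxel, measuring how much more that voxel activated under a
high cognitive load than a low one. A simple and interpretable way to turn
such maps into subject-level features is to threshold them (here at
t >= 3.17, one-sided p < 0.001 in the normal limit) and count, within each
parcel of an anatomical atlas (117 regions in the labelling scheme this
package emulates), how many voxels survive. The resulting subjects x regions
matrix of supra-threshold voxel counts feeds a penalized logistic
classifier that tries to separate two groups — here cases with chronic
fatigue syndrome versus sedentary controls, scanned before and after an
exercise stressor — and the claim "these groups differ" is then defended
not by the in-sample fit but by held-out accuracy, test-set subgroup
cross-validation, and a label-shuffle permutation test.

This package implements that pipeline end to end, plus a synthetic-cohort
generator so every stage is testable without subject data.

## The model

With region counts $x_1, \dots, x_i$ (standardized by training-set mean and
SD) and covariates age and sex, the classifier is the logit model

$$p(x) = \frac{1}{1 + e^{-(\beta_0 + \beta_1 x_1 + \cdots + \beta_i x_i)}}$$

fit by penalized maximum likelihood: we minimize the negative binomial
log-likelihood plus $\tfrac{\lambda}{2}\sum_{j \ge 1}\beta_j^2$ with the
intercept unpenalized. A subject is classified as a case when
$p(x) \ge 0.5$; the tie at exactly 0.5 goes to the positive class and the
threshold is never tuned.

Design choices worth knowing about:

* **Optimizer.** The default is a deterministic Newton/IRLS maximizer with
  backtracking, which is exactly reproducible and converges in a handful of
  iterations at these problem sizes. Logistic classifiers in this setting
  are often described as trained by stochastic gradient descent, so a seeded
  mini-batch SGD optimizer is available (`method = "sgd"`); it approximates
  the same optimum but is first-order, and ill-scaled unstandardized
  covariates slow it down considerably. Reproducibility and small-sample
  stability argue for the deterministic default.
* **Penalty.** Default $\lambda = 1/n$ — small enough to leave coefficients
  essentially unshrunk when the data identify them, large enough to keep the
  fit finite when ~50 training subjects and dozens of features produce
  perfect separation. With $\lambda = 0$ a separable fit warns and refits
  with a small fallback ridge rather than returning divergent coefficients.
* **Standardization.** Raw voxel counts span orders of magnitude across
  regions (parcel sizes differ wildly), so features are standardized with
  training-set means and SDs; the scaling is stored in the model and reused
  verbatim at prediction time. Test rows can never influence it — a test in
  the suite corrupts every test row and asserts the fit is unchanged.
* **Covariates.** Age and sex enter as predictors ("controlled in the model
  build" is read as inclusion), are exempt from feature elimination, and
  share the ridge penalty.

## Screening and selection

Before fitting, two screens run on the feature table:

1. **Collinearity.** Pearson correlations between all region pairs; any pair
   with $|R| \ge 0.9$ is flagged for removal/combination. The screen runs
   three times — training rows, test rows, and combined — since a small
   sample can hide a collinear pair in either portion. Zero-variance regions
   are reported and given $R = 0$ off-diagonal rather than propagating NaN.
   Pair summaries at the 0.7/0.8/0.9 levels use strict inequality
   ($R > \ell$); the removal rule uses $\ge 0.9$. The absolute value is used
   for the removal rule — the direction of a linear dependency is irrelevant
   to the multicollinearity problem.
2. **Recursive feature elimination.** On training rows only: fit the
   penalized logistic learner on all remaining features, drop the feature
   with the smallest absolute standardized coefficient, repeat until
   `n_target` remain. One feature per round; ties eliminate the
   lowest-index feature; a constant feature standardizes to zero and is
   always eliminated before any informative one. The default target is half
   the input features, mirroring the common library default when no target
   is given; it is exposed because at ~48 training subjects the
   events-per-variable heuristic argues for far fewer (roughly one feature
   per ten training cases, i.e. about 3–10 here).

## Splitting and validation

* **Stratified split.** Each class is sampled without replacement into the
  training set with per-class training count `round_half_up(ratio * class
  size)`. At the reference 70:30 split of 38 cases + 31 controls this gives
  27 + 22 training and 11 + 9 = 20 test subjects. The rounding rule is
  documented because the test-set size depends on it.
* **Ratio sweep.** `ratio_sweep()` re-runs the whole pipeline (split, RFE,
  fit, evaluate) across ratios 50:50–90:10 and several seeds, reporting
  mean/SD test accuracy per ratio and flagging ratios whose train-test gap
  exceeds a margin — the diagnostic that motivates preferring 70:30 over
  90:10.
* **Metrics.** Confusion counts with case = positive; accuracy,
  sensitivity, specificity, PPV, NPV as percentages. Zero-denominator
  ratios are reported as undefined (`NA`), never as 0. Printed values use
  one-decimal truncation (80.952 prints as 80.9); full precision is always
  stored. `solve_confusion()` inverts the process: it enumerates all
  integer confusion matrices of bounded size whose metrics reproduce a
  printed metric set — published tables demonstrably mix truncation and
  half-up rounding at one decimal, so a metric matches if either convention
  reproduces it.
* **Subgroup cross-validation.** The test set is partitioned (seeded) into
  k non-overlapping subgroups of near-equal size and the *fixed* fitted
  model is evaluated on each; nothing is refit. Size-weighted subgroup
  accuracies average exactly to the whole-test-set accuracy, which the
  suite checks as an identity.
* **Shuffle test.** Each permutation run shuffles the group labels, draws a
  fresh stratified 70:30 split of the shuffled sample, refits the logistic
  model on the shuffled training rows over the fixed selected-region set,
  and evaluates on the shuffled test rows. The empirical p is the raw
  fraction of runs with accuracy >= observed; if that count is zero after
  the first stage (default 1,000 runs) the test escalates (default 10,000
  more) and recomputes p over all runs executed. The raw ratio reproduces
  printed values like 11/10,000 = 0.0011; since it can be exactly 0, the
  add-one estimate (count+1)/(runs+1) is always reported alongside. The
  null mode is computed over the exact attainable accuracy grid k/n_test,
  not histogram bins. Re-running feature selection inside every permutation
  is the stricter variant (`reselect = TRUE`); the default keeps the
  selected set fixed, matching the reading that the same model structure is
  retrained per shuffle, and is two orders of magnitude cheaper.

## The synthetic cohort generator

`synth_config()` + `build_atlas()` + `generate_cohort()` emulate the study
conditions: 38 cases and 31 controls, 117 contiguous atlas parcels grown by
nearest-centroid assignment inside an ellipsoidal foreground on a 48^3 grid
at 2 mm spacing (~440 voxels per parcel — the order of magnitude of real
anatomical parcels at this resolution, which matters because spatial
smoothing makes the per-subject supra-threshold fraction noisier the
smaller the parcel), Gaussian t-value noise smoothed with sigma 1.27 voxels
(6 mm FWHM at 2 mm voxels), and covariates matching the published
demographics (age uniform on 18–70, i.e. mean 44 and SD 15; male rates
0.613 in controls, 0.263 in cases).

Effects are planted *at the feature level*: inside chosen regions, the mean
of the case group's t-values is shifted so that the expected fraction of
voxels at or above the threshold equals baseline + effect. Because the
smoothed noise is renormalized to exactly unit marginal variance (circular
FFT convolution, kernel L2 norm), this calibration is analytic, not
approximate: a planted +0.15 shift produces a +0.15 difference in expected
supra-threshold fraction, which the suite verifies by brute-force
averaging. The default plants +0.15 in five regions spread across the
atlas; the magnitudes are free parameters of the generator, not estimates
of any study's effects. A baseline fraction of 0.05 at t >= 3.17 was chosen
as a realistic supra-threshold load for a working-memory contrast.

What the generator does **not** emulate: hemodynamics, task timing, motion,
inter-subject anatomical variability, non-Gaussian noise, long-range
functional correlation between regions. Passing tests therefore show the
pipeline's statistical machinery behaves correctly (calibrated null,
recoverable planted signal), not that real cohorts are this separable.

## Sizing of the statistical property suites

Two properties are checked by simulation, with sizes chosen as the
package's own balance of Monte-Carlo error against runtime:

* **Type-I calibration.** 200 independent null cohorts (no planted effect,
  38 + 31 subjects, 117 regions on a 24^3 grid — under the null the grid
  only sets the noise scale, which exchangeability makes irrelevant), each
  analysed end to end with an RFE target of 10 (the events-per-variable
  choice) and a 200-permutation shuffle test. The fraction of experiments
  with p <= 0.05 must lie in [0.02, 0.09] around the nominal 0.05; the
  >= comparison with heavily tied discrete accuracies makes the test
  slightly conservative, so rates below 0.05 are expected.
* **Power and recovery.** Ten cohorts at the default planted effect, full
  default pipeline, 200-permutation shuffle test: at least 9/10 seeds must
  give test accuracy above 65% with p < 0.05, and at least 8/10 must place
  3+ of the 5 planted regions in the selected set.

## Degenerate inputs and numerical corner cases

* Baseline activation 0 maps to a zero mean shift, so a noise-free null
  config generates identically zero maps.
* Thresholding is inclusive (`t >= threshold`) by default — sources differ
  between ">= 3.17" and "> 3.17" — with a flag for strict comparison; only
  the positive tail is counted by default since the contrast of interest is
  one-sided activation.
* The t-to-p mapping requires degrees of freedom explicitly (`df = Inf` for
  the normal limit) rather than guessing a study's df.
* Regions absent from a subject's field of view count 0, not missing.
* `stratified_split` guarantees both sides of the split are non-empty per
  class even at extreme ratios.

## Known limitations

* The generator's planted effects are exchangeable across subjects within
  group; there is no subject-level random effect, so between-subject
  variance is purely voxel noise.
* Day-1/Day-2 analyses are independent runs over separate cohorts; no
  within-subject pairing across sessions is modelled.
* The permutation test fixes the selected-region set by default; with
  selection rerun per shuffle (`reselect = TRUE`) p-values are somewhat
  larger. Both are valid permutation schemes for the null of exchangeable
  labels *given selection performed on training rows only*.
* No ROC/AUC analysis, probability calibration, or class weighting; the
  decision threshold is fixed at 0.5.
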