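---
title: "Designing and stress-testing wildlife epigenetic clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and stress-testing wildlife epigenetic clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildclockr)
```

## The problem

Epigenetic clocks predict an animal's chronological age from DNA
methylation at CpG sites, almost always with an elastic-net regression of
age on a beta-value matrix. In wildlife work the training data are rarely
ideal: cohorts are small, skewed towards particular tissues, sexes,
populations or age bands, and the "known" ages are often themselves
estimates. Each of these defects degrades the clock in a characteristic
way. `wildclockr` provides (i) seeded simulators that generate methylation
cohorts with exactly these defects planted and known, (ii) the standard
clock fitting, feature-selection and validation machinery, and (iii)
replicated experiment harnesses that measure how much accuracy each defect
costs.

Everything is driven by explicit seeds: the same configuration and seed
give bit-identical matrices, splits and fits.

## Generative models

Two per-site models cover the age-methylation relationships used
throughout:

* **Linear:** `beta_i = x_i * age + eps`, with the site slope `x_i` drawn
  once from `Uniform(-0.1, 0.1)` and `eps ~ N(0, 0.5)`. Ages are assigned
  evenly across 0-30 years (a typical large-mammal lifespan), which
  matches the design of an age-structured cohort and removes one source
  of randomness.
* **Non-linear:** `beta_i = age^{x_i} + eps`, with `x_i ~ N(2, 0.35)` and
  `eps ~ N(0, 0.8)`. Methylation then changes much faster at some ages
  than others, which is what makes age-band extrapolation hard.

### The measurement scale matters

`clip_mode` selects the scale. `"raw"` reproduces the formulas verbatim;
the non-linear signal then spans roughly 0-900 arbitrary units, so the
fixed-sd noise is negligible and *every* training design — including
training only on old animals — recovers age almost perfectly (we measure
R^2 of about 0.99 for the old-biased design on that scale). Real beta
values are proportions. `"clip01"` therefore rescales each site's
noise-free trajectory affinely to [0.05, 0.95], adds the noise on that
scale and clips to [0, 1]. On the bounded scale the noise is material and
the age-bias pathologies appear: the old-trained clock's median test R^2
on young animals drops to roughly 0.33, with about triple the median
absolute error of an unbiased clock. The age-bias and ageing-error
harnesses default to `clip01` for this reason; `raw` remains the default
of the bare simulators for formula fidelity and closed-form tests.

### Planted defects

* `inject_class_bias()` adds zero-mean noise of sd `bias_extra_sd` to a
  seeded random fraction of sites, only for samples of one class. The
  magnitude of this "extra error" is a free parameter; the default equals
  the base noise sd, doubling the noise variance at affected sites —
  detectable without overwhelming the age signal.
* `inject_age_error()` perturbs `age_reported` with `N(0, sd)` draws while
  leaving `age_true` alone. All fitting routines train on reported ages
  when present and always evaluate against true ages, which is what makes
  ageing-error experiments meaningful. Negative reported ages are kept by
  default (the perturbation is exactly normal); a truncation flag exists.
* `simulate_structured_cohort()` overlays factor labels (tissue, sex,
  population, ...) at designed proportions and plants class effects —
  additive shifts and/or slope multipliers at chosen sites — recording
  the affected site IDs so that filter power and size can be measured
  against known truth. Default effect sizes in the tests use a 0.3-unit
  shift against sd-0.5 residuals at n = 400, a moderate effect with
  >95% theoretical power at p < 0.001.

## Clock fitting

`fit_clock()` wraps `glmnet` with the conventions used for published
clocks: internal predictor standardization with coefficients reported on
the original beta scale, mixing parameter `alpha = 0.5` by default
(neither pure ridge nor pure lasso; the convention when nothing is known
about the correlation structure), and penalty strength chosen by seeded
k-fold cross-validation at the MSE minimum (`lambda.1se` available as a
conservative option; ties on the CV curve resolve to the largest, most
parsimonious lambda by construction of the decreasing path). An explicit
`lambda` skips cross-validation and makes the fit a pure function of the
data — the mode used wherever exact reproducibility across validation
loops is asserted. Fixed-lambda fits run on a short warm-started path
ending at the target, which is both faster and better-converged in
`glmnet` than a cold single-lambda call.

Age acceleration is reported in both of the field's forms: the raw delta
(epigenetic minus chronological age) and the residual from regressing
epigenetic on chronological age within the evaluated set.

## Feature selection

Four reducers, all returning an exhaustive site-by-site report:

* alignment keep-lists (`filter_by_alignment`), the stand-in for genome
  alignment of a multi-species array;
* per-site OLS models of methylation on age plus class factors
  (`fit_sitewise_models`), with exact F-tests per factor, vectorised by
  sharing one QR decomposition across all sites — a deliberate choice of
  exact small-sample tests over moderated (empirical-Bayes) statistics,
  so counts on real array data will differ slightly from
  moderated-statistic pipelines;
* exclusion of class-biased sites at a raw `p < 0.001` with no
  multiple-testing correction (`exclude_class_biased_sites`) — the
  conventional screen, whose false-exclusion rate on null sites is then
  simply the threshold (verified against the binomial in the tests);
* retention of sites age-associated within *every* level of a grouping
  factor (`retain_age_associated_sites`, intersection rule, default
  threshold 0.001 for consistency with the class screen) and an
  unsupervised variance filter with deterministic ID-ordered tie-breaks.

## Validation

`holdout_validate()`, `kfold_cv()` and `loo_cv()` (sample-wise or
group-wise) share fit settings and pool out-of-fold predictions into a
single metric set — pooling, rather than per-fold averaging, matches how
leave-one-out results are reported for small wildlife cohorts. Accuracy
is summarised by the median absolute error, Pearson's r and its square;
R^2 is deliberately the squared correlation (identical to the simple
regression R^2), so a badly calibrated clock can still show a high R^2 —
the two metrics answer different questions. Replicate-level uncertainty
uses percentile (2.5/97.5, type-7) intervals for reproducibility.

## The experiment harnesses

Each `run_*` harness derives per-replicate seeds from one master seed,
covers its grid completely (failures are recorded as rows, never
dropped), and returns a tidy table with provenance columns.

* **Class bias** (`run_class_bias_sweep`): two classes spanning the full
  age range; the biased class carries extra noise at a swept fraction of
  sites. A mixed clock (150 + 150 per class) is compared against a
  biased-only clock, size-matched at 300 training samples so that
  composition is not confounded with training-set size; with the extra
  noise switched off the two arms are then exchangeable by construction.
  Both evaluate on 150 unbiased samples.
* **Age bands** (`run_age_scenarios`): unbiased, young-trained,
  old-trained and prime-age-trained clocks on the non-linear cohort.
* **Ageing error by sample size** (`run_error_by_n_grid`): full factorial
  over error sd and total n, training on reported ages, scoring against
  truth.
* **Class overlap** (`run_overlap_sweep`): training sets with a
  controlled fraction of samples from the test set's class; exhausted
  class pools fall back to with-replacement sampling with a warning.
* **Feature selection** (`run_feature_selection_sweep` and
  `run_selection_ladder`): removing known-biased sites versus retaining
  them, and the standard ladder from "no selection" through alignment and
  per-group age filters to the full stack, recording surviving site
  counts per rung.
* **Validation schemes** (`run_validation_comparison`): paired hold-out
  and leave-one-out estimates over repeated subsets. A full internal
  cross-validation inside every leave-one-out fold would cost n fits per
  fold; the default picks lambda once per repetition on the whole subset
  and holds it fixed across folds (`loo_lambda = "cv"` restores the
  expensive exact protocol).

## Numerical and design notes

* Biased-site counts use round-half-away-from-zero; site selection is
  seeded and without replacement.
* Per-site OLS slope and F statistics are computed against an explicit
  `lm()`/`drop1()` loop in the tests to 1e-10.
* The ridge fit at vanishing penalty reproduces the least-squares closed
  form to 1e-6 (with a tightened convergence threshold).
* Clock JSON serialization writes doubles at 17 significant digits, so a
  reloaded clock predicts bit-identically.
* Whether simulated ages should be integers is unstated in the designs
  this package emulates; continuous evenly spaced ages are used.

### Choosing the cohort for the scheme-comparison experiment

The hold-out versus leave-one-out comparison is run, in the acceptance
tests, on a 20-site age-informative panel with 2-year ageing error, 400
samples per repetition and a 250/150 split over 50 repetitions. The
reasoning: with a large unsaturated site panel, a clock trained on 399
samples is genuinely slightly better than one trained on 250, and a
paired test over 50 repetitions reliably detects that learning-curve
slope — the comparison would then measure training-set size, not the
validation scheme. A finished clock (tens of sites carrying weight,
accuracy limited by ageing error rather than by sample count) sits on the
plateau of its learning curve, and only there is "leave-one-out equals
hold-out" a property of the *scheme*. That plateau regime is what the
experiment emulates; on steep learning curves the schemes genuinely
differ, and the package will show that difference rather than hide it.

## What the simulations do not capture

No array chemistry, probe intensities, detection p-values, normalisation
artefacts or batch structure are simulated; sites are generated
independently, so the strong inter-site correlation of real methylomes
(and the arbitrariness it induces in elastic-net site choice) is absent;
class effects are simple shifts and slope multipliers. Passing tests
therefore demonstrate that the *procedures* behave as designed under
known truth, not that any particular real cohort is free of the biases
probed here.

## Problem sizes

The test suite runs the experiments at 40-500 sites, 50-600 samples and
25-50 replicates per condition; the headline old-biased-clock figure uses
the canonical 500 sites x 300 samples over 50 replicates, matching the
design it reproduces. All replicate counts are arguments and default to
100 in the exported harnesses.
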