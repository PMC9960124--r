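---
title: "Methods: breath VOC ratio screening and diagnostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath VOC ratio screening and diagnostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathratio)
```

## The analysis problem

Exhaled breath sampled into bags and analysed by thermal-desorption GC-MS
yields, per subject, a vector of integrated peak areas for a few dozen
volatile organic compounds (VOCs). Three features of such data drive every
design choice in this package:

* **Exogenous background.** Room air contains many of the same compounds,
  so each breath sample is paired with an ambient sample taken the same day.
* **Censoring.** A compound is often simply not detected; peak tables are
  zero-inflated, and the zero pattern itself differs between groups.
* **Scale variability.** Absolute areas vary with sampling volume and
  instrument response, which is why *ratios* of peak areas to reliably
  detected "main" compounds are used as features.

All of this makes peak areas heavy-tailed and non-normal, so associations
are measured nonparametrically throughout (Spearman's ρ).

## Preprocessing rules and their parameters

| parameter | default | meaning |
|---|---|---|
| `min_excess` | 0.20 | detected in a sample iff breath ≥ (1+0.20) × ambient and > 0 |
| `min_occurrence` | 0.50 | retained iff detected in **more than** 50% of samples (strict) |
| `denominator_occurrence` | 0.86 | denominator iff per-group frequency ≥ 86% in *both* groups |
| `blocklist` | phenol, N,N-dimethylacetamide | known sampling-bag storage contaminants, dropped outright |

Two readings of the 20% rule are possible (per sample, or on aggregated
areas); we apply it **per sample**, so that the same detection events feed
both the occurrence filter and the frequency report — one coherent
definition of "detected". The occurrence filter is computed over all samples
pooled; per-group frequencies are used only for denominator eligibility and
reporting, since denominators must be safe in *both* groups. Both choices
are configurable.

Ratios are built as corrected numerator over corrected denominator. A zero
numerator gives a ratio of 0 (the compound is absent); a zero denominator
gives a **masked missing value**. Denominator choice makes such zeros rare
by construction, and masking (with pairwise-complete deletion in the screen,
training-median imputation only inside model fitting) preserves that intent
rather than inventing a number. On the default denominator threshold the
built-in 40-compound occurrence panel yields exactly ten denominators, with
acetonitrile (87%/88%) the least frequent qualifier and 2-butanone (76%/86%)
the first compound excluded; at a 100% requirement only acetone, isoprene
and dimethyl sulfide remain.

## The association screen

`spearman_rho()` ranks with average ties and computes
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) against a t distribution with \(n-2\)
degrees of freedom, two-sided (p = 0 at |ρ| = 1). This matches the
asymptotic method of `stats::cor.test` to 1e-12 in ρ and 1e-9 in p (a test
enforces this on 1000 random vectors with and without ties). An exact
permutation p-value is available for n ≤ 8 by full enumeration; beyond that
the factorial explodes and the t approximation is already accurate, so no
sampled permutation scheme is provided. No multiple-testing correction is
applied by default — the screen is deliberately a raw-α filter at 0.05,
since its purpose is conservative *exclusion* of confounded features, where
a correction would make exclusion laxer.

Factor encodings (`encode_factor()`): disease 0/1 on all samples; treatment
(before/under), each comorbidity flag, localization and histology on cancer
samples only. Histology is ranked by malignant course — squamous 1,
adeno 2, small-cell 3 — and non-differentiated tumors, which have no place
on that ordinal scale, are masked out. TNM codes are scored
lexicographically (T, then N, then M) via T·100 + N·10 + M; any monotone
scoring of the lexicographic order gives identical Spearman results, and
alternative encodings can be screened by passing a custom feature. The
localization orientation (central = 1) is a reporting convention,
flippable with `central_high = FALSE`; only the sign of ρ changes.

A feature significant against treatment or any comorbidity is excluded from
biomarker candidacy (`exclude_confounded()`), with the triggering factors
recorded. The survivors are ranked by |ρ| against disease; ties break
lexicographically so selection is deterministic. Selected features are then
checked for age association *within* each group separately
(`check_age_independence()`), because case and control groups typically
differ in age and a pooled age correlation would be confounded with disease
itself.

The companion power analysis uses the Fisher-z closed form
\(n = ((z_{1-\alpha/2} + z_{power})/\mathrm{atanh}\,\rho_0)^2 + 3\), rounded,
floored at 4; at ρ₀ = 0.2, α = 0.05, power 0.85 it gives n = 221.

## Diagnostic models

**GBDT.** Stagewise additive logistic regression: initialise at the
base-rate log-odds, then at each of 200 stages fit a depth-≤3 regression
tree to the negative gradient \(y - p\). Splits maximise variance reduction
with an exhaustive threshold search over sorted unique values; ties go to
the first feature index and the smallest threshold, so fits are exactly
reproducible with no random element. Leaf values are one Newton step
\(\sum r / \sum p(1-p)\), clipped to ±4 for stability, shrunk by a 0.1
learning rate. All hyperparameters are conventional small-cohort defaults
and exposed in the interface. Variable importance is the accumulated
squared-error improvement per feature over all splits, rescaled so the
maximum is 100 — features never split on score exactly 0.

**MLP.** A 12–5–2 network (logistic hidden layer, softmax output) trained by
minimising full-batch cross-entropy with full-memory BFGS — at 77 weights
there is no reason for a limited-memory variant — using Armijo backtracking
(sufficient-decrease constant 1e-4, halving steps), curvature-guarded
inverse-Hessian updates and a steepest-descent reset if descent is lost.
Training stops at a gradient max-norm of 1e-6 or 500 iterations. Inputs are
standardized with training-split constants. Weight initialisation is
Gaussian (sd 0.5) under a caller-supplied seed; a non-finite loss triggers
up to three restarts at a quarter of the scale. Activation and output
choices are declared assumptions in the spirit of classic small-cohort MLP
classifiers, not recovered settings of any particular software. The
analytic gradient is verified against central finite differences in the
test suite.

Hard labels use the 0.5 probability threshold; an exactly tied probability
is called as the cancer class, the conservative direction for a diagnostic.

**Evaluation.** "Three datasets" are implemented as three independent
seeded stratified 70/30 partitions — the natural reading when a 70/30 split
is the stated design and results are reported per dataset; a true k-fold
mode is available behind `eval_config(kfold = TRUE)` for the other reading.
Per-class training counts are `floor(n_class × 0.7)` (112 + 120 samples
give a 162/70 split). Sensitivity and specificity are reported in percent;
an empty denominator yields NA, never a fabricated 0.

## The synthetic cohort generator

The generator is the package's test bed and demonstration data source. It
emulates:

* per-group detection frequencies for a 40-compound reference panel
  (detection is a Bernoulli draw per sample; non-detection is stored as 0);
* log-normal positive areas, `log_sd = 0.8`, with per-VOC `log_mean`
  staggered over e¹¹–e¹⁵ — typical EIC peak-area magnitudes, more frequent
  compounds more abundant;
* paired ambient rows at 15% of the breath level by default (configurable,
  including a many-to-one day mapping);
* a count-based covariate model for a 112 + 120 reference cohort: sex,
  smoking, treatment status (96 of 112 under treatment), comorbidity
  counts, 24 TNM codes at tabulated frequencies, histology and
  localization counts — comorbidity flags and tumor descriptors exist only
  in the cancer group. Ages are stand-ins chosen to reproduce the medians
  and ranges (controls median 21 with a decaying older tail, patients
  normal around 63); counts scale proportionally with group size;
* injectable effects: for a target Spearman ρ between a VOC and a factor,
  the latent log-area is driven by λ·s(f) + √(1−λ²)·ε, where s(f) is the
  standardized normal score of the factor (midrank convention under ties)
  and λ is calibrated by root-finding on the exact population map from λ to
  Spearman ρ under the factor's empirical tie structure (closed form
  2·sin(πρ/6) for effectively continuous factors). Because ranks are
  controlled, any monotone transform of the latent score — including the
  log-normal area map — carries the same ρ. Binary factors cap the
  achievable |ρ| (at √3/2 for a balanced split); unreachable targets are
  refused rather than silently attenuated. Several effects on one VOC
  combine additively on the latent scale with marginally calibrated λs
  (requiring Σλ² < 1), an approximation that is exact for independent
  factors. Effects named for a *ratio* are injected into the numerator VOC;
  the realised ratio correlation is then an outcome, not a controlled
  quantity.

What the generator does **not** emulate: chromatographic artifacts,
retention-time drift, batch effects, inter-VOC metabolic correlation
beyond shared factor effects, storage-bag contamination dynamics, or any
estimate of the real study's peak-area distributions (no such distributions
are published). Passing tests therefore certify the *machinery* — filters,
screen calibration, classifier behaviour — under a controlled data model,
not clinical performance on real breath data.

## Numerical and testing choices

* Fixed seeds make every cohort, split and fit bit-reproducible; the
  pipeline manifest records MD5s of all artifacts and reruns are
  byte-identical.
* Recovery checks use the Fisher-z interval with the rank-correlation
  variance 1.06/(n−3) (the Fieller–Hartley–Pearson correction), the
  standard interval for Spearman's ρ.
* Test problem sizes are chosen for statistical head-room at fixed seeds:
  frequency recovery at 2000/group (a 4-point tolerance is ≈3.6σ), effect
  recovery over 20 replicates at 1000/group, the screen's type-I error over
  2000 null features at n = 400, classifier separation at |ρ| = 0.75 on six
  fully detected VOCs at 400/group. The demonstration pipeline uses
  200 + 200 samples with |ρ| ≈ 0.15–0.29 effects, the magnitude range
  typical of breath VOC case-control screens; at that signal strength
  held-out accuracy in the 60–75% range is the expected behaviour, and the
  run completes in a few seconds.
* Degenerate inputs are signalled, not patched: constant factors or
  fewer than 3 complete pairs give NA screen rows; single-class labels,
  unreachable injection targets and misaligned tables are errors naming
  the offending object.

## Known limitations

* The exact permutation p-value stops at n = 8 (enumeration only).
* Confounder screens run on cancer samples only (where comorbidities are
  recorded); with comorbidity flags absent for controls, a pooled screen
  would conflate comorbidity with disease status.
* The multi-effect injection is marginally calibrated; strongly correlated
  factors (e.g. TNM and histology on the same VOC) would bias joint
  targets.
* GBDT deviance non-increase is a property of the shrunken Newton steps at
  the default learning rate; it is asserted in tests, not proven for
  adversarial settings.
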