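---
title: "Readiness-for-discharge classification: models, synthetic world and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Readiness-for-discharge classification: models, synthetic world and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuready)
```

## The problem

Intensive care units discharge patients through a manual review process
anchored at *callout* — the recorded moment a clinician declares a patient
ready to leave the unit. `icuready` implements a retrospective pipeline for
building and evaluating classifiers of readiness-for-discharge (RFD): it
codifies a classical set of fifteen nurse-led discharge (NLD) criteria as
thresholded tests, turns historical stays into labelled instances, extracts
windowed physiological features, and compares rule-based scores against
regularised logistic and random-forest classifiers trained across two
source cohorts.

Because real critical-care datasets are access-restricted, the package
ships a synthetic two-cohort EHR generator with a *planted*, known
physiology-to-outcome model. Every downstream stage — labelling, feature
extraction, tuning, evaluation — is exercised and tested against this
stated world.

## Labels

An instance is a (stay, reference time) pair.

* **Callout instances.** A stay is RFD at callout iff the patient left
  hospital alive and was never readmitted to the ICU during the same
  hospital admission; in-hospital death and/or readmission makes the
  callout instance NRFD. A 48-hour readmission window variant is a
  deliberate non-goal.
* **Augmented negatives.** Negative outcomes are rare (about 12.6% and
  5.8% in the two emulated cohorts), so the negative class is augmented
  with instances sampled uniformly from 3–8 days *before* callout — under
  the assumption that the patient still required critical care then,
  whatever their eventual outcome — excluding the first 24 h of the stay.
  Augmentation proceeds one instance per eligible stay before any stay is
  reused (reuse minimises within-patient correlation and happens only when
  parity cannot otherwise be reached), and stops at class parity per
  source cohort.

## Features

Eighteen base features mirror the criteria variables: paired window
extremes (`resp_min`/`resp_max`, `hr_min`/`hr_max`, `temp_min`/`temp_max`),
conservative single extremes (`fio2` and `pain` maxima; `spo2_min`,
`bp_min`, `gcs_min`, `airway` minima), and most-recent laboratory values
(`hco3`, `haemoglobin`, `k`, `na`, `creatinine`, `bun`). The extended set
adds `age`, `sex`, `bmi` and `hours_since_admission`.

Windows are half-open `(t_ref - 4 h, t_ref]`, so an observation exactly at
the reference time counts once; if a variable has no sample in 4 h, a 36 h
fallback window is used (labs are drawn roughly twice a day, so this is
the normal path for them). A variable absent from both windows becomes a
missing marker.

Two choices here were genuinely open and are therefore explicit,
overridable defaults:

* *Aggregation direction for single-feature vitals.* The criteria bound
  each variable on its failing side, so the window aggregate is the
  clinically conservative extreme (worst value in window): maximum FiO2 and
  pain, minimum SpO2, systolic blood pressure, coma score and airway
  patency. Laboratory tests use the most recent draw since trends in slow
  analytes are not what the criteria test.
* *Missing inputs fail their test.* When a criteria test's feature is
  missing, the test fails and is flagged in the result. The alternative
  (skip-and-renormalise) silently inflates scores for sparsely monitored
  patients; with upstream imputation the case is rare anyway.

Imputation is k-nearest-neighbour (default `k = 5`, configurable):
Euclidean distance over mutually observed features after internal
standardisation, rescaled by the fraction of usable coordinates, donors
restricted to rows observing the target feature, ties broken by row order.
Model matrices are then standardised with means and SDs fitted on the
*training* rows only — the leakage-free choice — with zero-variance
columns mapped to 0. A complete-case mode (`imputation = "complete"`)
drops incomplete instances instead, as a sensitivity analysis.

## Rule-based scores

`evaluate_tests()` applies the fifteen tests with inclusive bounds exactly
as codified (e.g. FiO2 at 0.60 passes). The count score is
`n_passed / 15`, a 16-valued probability-like output whose threshold family
"at least k of 15" traces the criteria's ROC curve. The weighted score
replaces uniform weights with per-test weights built from feature
importances: each test's weight is the sum of its constituent features'
importances, floored at zero and normalised to one. In the pipeline those
importances are the logistic classifier's permutation importances from the
same data split, so the weighted criteria remain interpretable while
borrowing strength from the trained model.

`sustained_rfd()` implements the original deployment rule — all fifteen
criteria held for a trailing 4 h window. Data are discrete samples, so the
rule is evaluated on the observation grid: every in-window observation of
each variable must satisfy its bounds, and a variable with no in-window
observation fails as missing. The reading that all criteria must hold
*concurrently* throughout the window (rather than each criterion
individually sustained at some point) follows the original specification
of the rule.

## Classifiers and the multiple-source protocol

Two families are deliberately simple and interpretable:

* **Logistic (LC).** Ridge-penalised logistic regression (glmnet). The
  penalty `lambda` is the single tuned hyperparameter, over a log-spaced
  grid ordered strongest-first.
* **Random forest (RF).** A native C++ CART forest (gini splits, per-node
  `mtry = floor(sqrt(p))` feature subsampling, bootstrap bagging,
  leaf-probability averaging). The grid tunes depth and leaf size. No RF
  implementation exists in the target environment, so the forest is part
  of the package; its randomness comes from R's RNG stream, making fits
  seed-reproducible.

One split of the protocol: hold out 30% of the smaller (gicu-like) cohort
for testing and an *equal-sized* test set from the larger cohort; tune by
two-fold multiple-source cross-validation (train on the fold drawn wholly
from one source, score AUROC on the other, both directions, maximise the
fold mean; ties resolve toward the simpler model); retrain the winner on
the pooled training data; evaluate per-cohort; compute permutation
importances (mean AUROC drop over independent column permutations) on the
pooled held-out data. The experiment repeats over `n_splits` random splits
(100 at study scale) and reports per-metric means and SDs; a single-split
run reports SDs as 0 and is flagged. One master seed derives per-split
child seeds, so a full experiment is reproducible bit-for-bit.

AUROC is assumed as the tuning objective; it is the headline metric of the
evaluation suite and the quantity the importance procedure perturbs.

## Evaluation suite

`metric_report()` computes AUROC, partial AUROC over FPR ≤ 0.3 (maximum
0.3; the chance diagonal scores 0.045), Brier score, and operating-point
metrics at specificity 0.7 located by linear interpolation between the two
adjacent ROC points. Accuracy and F1 at this virtual threshold use
fractional confusion entries — with prevalence $p$, sensitivity $se$ and
specificity $sp$:

$$\mathrm{acc} = p\,se + (1-p)\,sp,\qquad
F_1 = \frac{2\,p\,se}{2\,p\,se + (1-p)(1-sp) + p\,(1-se)}.$$

The realised-threshold alternative (snap to the nearest achievable
operating point) is available through the reported threshold mixture, but
interpolation is the default as the continuous-consistent choice.
Trapezoidal integration and midrank tie handling are used throughout;
AUROC is property-tested against a brute-force concordant-pair oracle, and
the Spearman agreement statistic reproduces the published value (0.761)
when fed the published rank columns.

## The synthetic world

The generator emulates two cohorts whose demographic, event-timing and
outcome parameters default to the published cohort characteristics:
sizes 7592 / 1870, percent female 47.6 / 40.5, median (IQR) age, BMI,
length of stay and discharge delay, and mortality / readmission /
composite negative-outcome rates of 6.14 / 7.76 / 12.57% (mimic-like) and
3.58 / 2.78 / 5.83% (gicu-like). Quantities given as median (IQR) are
drawn from log-normals fitted to those statistics (stay lengths are
right-skewed). Timestamps are integer minutes since admission; vitals
default to hourly sampling, laboratory variables to every 12 h; each
scheduled sample drops independently with probability 0.05 — enough to
exercise the 36 h fallback and imputation paths without dominating them.

Each variable follows *baseline + recovery ramp + AR(1) noise*: a
per-patient derangement amplitude (severity-scaled, in the variable's
failing direction; the sodium band can deviate either way) decays linearly
to a per-patient *stall* level at callout and holds thereafter. Stall
fractions are Beta(1.2, 8) distributed: most patients recover essentially
fully by callout, a minority remain measurably short of their normal band.
GCS is rounded to integers in 3–15, pain to 0–10, FiO2 is titrated in 0.05
steps on [0.21, 1] (a clinician-set variable, not a continuous
measurement), SpO2 capped at 100, and airway patency is a noisy threshold
on the recovery state. Coma score is generated as the cleanest signal
(large amplitude, low observation noise) with airway second — the two
markers a clinician would call the clearest evidence of continued critical
illness.

Outcome flags are drawn from a logistic model *on the generated data
itself*: the 18 features are extracted at callout, standardised across the
cohort, combined with the planted coefficients (largest on `gcs_min`, then
`fio2`, then `airway`; every sign aligned with the variable's derangement
direction), and the intercept is calibrated by root-finding so the
expected negative-outcome fraction equals the configured composite rate.
Negatives are then split into death and/or readmission by overlapping
uniform sub-intervals so both marginal rates and the composite are
honoured simultaneously.

What a green test does — and does not — establish. The synthetic world has
a monotone, low-dimensional recovery signal; real EHR data have
interventions that mask physiology (controlled ventilation, vasopressors),
patient-subtype heterogeneity, informative missingness and
documentation artefacts, none of which are modelled. Green acceptance
tests therefore establish that the pipeline's machinery is correct (rule
codification, labelling windows, split protocol, metric identities,
parameter recovery) and that the planted signal is recovered in the
expected order (classifiers ≥ weighted criteria ≥ uniform criteria;
`gcs_min` the top-ranked feature for both families). They do not establish
clinical performance; the published real-data AUROCs (≈0.87–0.89) are not
reproducible from synthetic data and are not targeted.

## Numerical choices and degenerate inputs

* Inclusive bounds everywhere in the criteria; a record sitting exactly on
  every printed bound passes all fifteen tests.
* ROC sweeps group tied scores at one threshold; constant scorers give
  exactly AUROC 0.5.
* Tuning ties (within 1e-12) resolve to the earlier grid entry; grids are
  ordered simple-to-complex.
* Zero-variance features standardise to 0; fully-missing feature columns
  are an error naming the feature.
* Stays whose augmentation window `[callout - 8 d, callout - 3 d] ∩
  [admission + 24 h, ∞)` is empty contribute no augmented instance;
  exhausted pools yield fewer instances than requested, with the shortfall
  recorded.
* `n_splits = 1` reports SDs of 0 with a flag rather than NA.
* Negative-rate 0 skips the outcome model entirely (no negatives).

## Known limitations

* The forest uses axis-aligned gini CART without out-of-bag machinery or
  honest splitting; it is adequate for the comparative protocol, not a
  general-purpose RF replacement.
* kNN imputation is O(n²) in instances; fine at cohort scale here.
* The generator does not model interventions, diagnosis codes or severity
  scores (explicit non-goals), nor inter-variable correlation beyond the
  shared severity/stall factors.
* Augmented instances reuse stays when parity demands it; heavy reuse
  inflates within-patient correlation relative to drawing from a larger
  pool of real patients.
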