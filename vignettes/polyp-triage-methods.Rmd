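---
title: "Methods: non-invasive triage modelling for polyp surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-invasive triage modelling for polyp surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyptriage)
```

## The problem

Patients on colorectal polyp surveillance are re-scoped at fixed intervals,
and a large share of those colonoscopies find nothing that changes
management. Two non-invasive markers can triage this queue: a quantitative
faecal immunochemical test (FIT, µg Hb/g faeces) and a urinary volatile
organic compound (VOC) classifier score in [0, 1]. The clinical outcome is
a binary *high-risk finding*: at least two premalignant polyps including at
least one advanced polyp, or at least five premalignant polyps. In the
surveillance population modelled here the prevalence of a high-risk finding
is 0.26, and a colonoscopy is treated as a perfect gold standard.

`polyptriage` implements the full evaluation pipeline for this setting:
threshold-level diagnostic accuracy, ROC operating points with trapezoidal
AUC, the likelihood-ratio calculus for combining the two tests serially or
in parallel, per-1000-patient accounting of the resulting colonoscopy
demand, and a cross-validation harness for score-based classifiers. Because
no patient-level data are published for this setting, the package also
ships a calibrated synthetic cohort generator so that every stage can be
exercised and tested end to end.

## Synthetic cohort: what is calibrated, and what is not

The generator draws, per subject, a Bernoulli(prevalence) high-risk status
and then class-conditional marker values:

* FIT is **log-normal** within each class. FIT is strongly right-skewed
  (cohort mean 44.9 against SD 124.1 in this population), and the
  log-normal is the minimal two-parameter family on the positive half-line
  that can match two survival-function anchors exactly, in closed form via
  normal quantiles of the log-threshold (`calibrate_fit_model()`).
* The VOC score is **Beta** within each class — the minimal two-parameter
  family on [0, 1]. Its two anchors are solved numerically (Nelder–Mead on
  the log-shapes, multi-start, residual tolerance 1e-6,
  `calibrate_voc_model()`).

Each class-conditional model is pinned to two published exceedance
anchors, chosen to straddle the clinically used operating range and to
prefer integer counts over rounded rates where both are available
(`calibration_targets()`): for FIT, P(X ≥ 10) = 37/68 and P(X ≥ 80) =
17/68 in the high-risk class, P(X ≥ 3) = 64/187 and P(X ≥ 10) = 39/187 in
the low-risk class; for VOC, P(S ≥ 0.88) = 0.94 and P(S ≥ 0.94) = 0.66
versus P(S ≥ 0.81) = 0.46 and P(S ≥ 0.88) = 0.31.

Given disease status, FIT and VOC are drawn **independently** by default.
No joint distribution of the two markers has been published, and
conditional independence is also what the serial-testing arithmetic
assumes, so the default makes the generator consistent with the analytical
pipeline it feeds. A Gaussian-copula correlation (`rho`) is exposed purely
for sensitivity analysis. Note that even at `rho = 0` the markers are
*marginally* correlated across the cohort, because both are elevated in
the diseased class; independence holds within class.

Disease status is i.i.d. Bernoulli by default; `fixed_counts = TRUE`
forces exactly `round(n × prevalence)` cases, which is what the
table-reproduction drivers use (68/255). A single integer seed makes
`generate_cohort()` a pure function of its inputs; the caller's RNG state
is saved and restored.

What the generator does **not** emulate: age, sex, BMI, smoking or
medication covariates; sensor-level VOC signals; any marker measurement
error beyond the fitted families. Tests passing on synthetic cohorts
therefore validate the *pipeline arithmetic and calibration*, not the
clinical performance claims, which enter only through the published
operating points taken as inputs.

## Diagnostic accuracy conventions

* **Positivity** is inclusive: a subject is test-positive iff the marker
  value is ≥ the cut-off. An assay whose lowest detection limit (3 µg
  Hb/g) is itself used as a cut-off implies the inclusive reading; the
  strict alternative is available via `inclusive = FALSE`.
* **Intervals**: Wilson score by default, Clopper–Pearson optionally
  (`ci_proportion()`). The published interval estimates for this setting
  are internally inconsistent between their summary and table forms, so no
  single method reproduces all of them; intervals are reported but are not
  reproduction targets.
* **Predictive values**: `performance()` reports the count ratios
  tp/(tp+fp) and tn/(tn+fn) *and* the prevalence-form Bayes identities
  (`ppv_bayes`, `npv_bayes`). On raw counts the two coincide
  algebraically. The published accuracy table, however, derives its
  predictive values by applying the Bayes identity to the *2-dp rounded*
  sensitivity/specificity (e.g. 0.54/0.79 at the 10 µg cut-off gives PPV
  0.475 → 0.47, where the raw ratio 37/76 = 0.487 would print as 0.49).
  `predictive_values()` applied to display-rounded inputs is therefore the
  table's convention, and is what the reproduction drivers use. A few
  printed cells in non-headline rows (e.g. 16/68 shown as 0.23) appear to
  round inconsistently; they are not used as targets.
* **AUC** is the trapezoid over empirical operating points sorted by false
  positive rate (ties broken by true positive rate ascending), with (0,0)
  and (1,1) anchors appended by default. This reconstruction reproduces
  the published FIT AUC of 0.67 from the eight tabulated operating points,
  so threshold-based integration is adopted; no smoothed or binormal fit
  is attempted, and no AUC interval is computed.
* **Display rounding** throughout is 2 decimal places (or whole percent),
  half away from zero (`round_half_up()`), matching table formatting;
  `base::round()`'s half-to-even would differ on exact halves.

## Likelihood-ratio (Fagan) calculus

A test with sensitivity *s* and specificity *c* has LR+ = s/(1−c) and
LR− = (1−s)/c; post-test odds are pre-test odds times the LR
(`fagan_update()`). All propagation is in full precision; the
whole-percent figures are display-only. `serial_chain()` follows the
rule-out path: each test is given only to patients negative so far, so
stage i+1's pre-test probability is stage i's post-negative probability.
At prevalence 0.26 the VOC(0.94/0.69)-then-FIT(0.54/0.79) chain gives
52% after a positive VOC, 3% after a negative VOC, 2% after both
negatives — a 24-point reduction. An optional
`display_rounded_propagation` mode rounds each stage's input to a whole
percent, mimicking reading intermediates off a printed nomogram; both
modes reproduce the published whole-percent figures, and full precision is
the canonical default.

Positive results leave the chain for colonoscopy — they are accounted in
the cohort flow, not updated further. Pre-test probabilities of exactly 0
or 1 are fixed points, returned unchanged.

`parallel_combine()` handles both tests given together ("negative" means
both negative). Under conditional independence, combined sensitivity is
1−(1−s₁)(1−s₂) = 0.97 for these two tests, and combined specificity would
be the product 0.69 × 0.79 = 0.545. The published combined *specificity*
of 0.11, by contrast, comes from a classifier jointly retrained on both
markers, whose internals are not published; it is therefore accepted as a
supplied constant (`mode = "supplied"`), never re-derived, and the
independence product is clearly labelled a model assumption. The
independence figure is used only for the combined-sensitivity check.

## Per-1000 cohort flow

`flow_single_stage()`, `flow_serial()` and `flow_colonoscopy_all()` do
expected-frequency accounting for 1000 patients. The rounding protocol
matters: each reported cell is rounded half away from zero to a whole
patient, and the *rounded* diseased-in-negatives count (16 after VOC)
flows into stage 2. This is the only protocol that reproduces the
published per-1000 table in every cell simultaneously — propagating
unrounded expectations gives 8.4 stage-2 detections where the table
prints 9. Unrounded expectations are retained in `*_raw` columns, where
the identities detected + missed = n×prevalence and (missed / negatives)
= post-negative probability hold exactly; both are property-tested.
Number needed to scope is colonoscopies per finding detected, rounded to
the nearest whole number (590/253 → 2; 1000/260 → 4), with the real ratio
kept in `nns_exact`.

## Cross-validation harness

The published VOC classifier is a neural-network pattern recogniser with
no released architecture, weights or raw signals, so its AUC (0.74) and
the combined-model AUC (0.61) cannot be recomputed and are not targets.
What *is* reproducible is the evaluation harness around it: a seeded
3-fold split (k = 3 for a cohort of 255 gives folds of 85), training on
k−1 folds, scoring the held-out fold, and pooling out-of-fold scores into
a single ROC rather than averaging per-fold curves — pooling matches the
reporting of one AUC for the whole cohort. The learner is injectable; the
default is a logistic score model (`learner_logistic()`), a deliberately
plain stand-in whose job is to be monotone in the informative features.
Fold randomisation is a plain seeded shuffle by default, with a stratified
option; if a training set would contain a single class, folds are
reassigned with stratification and a warning. `choose_threshold()` offers
Youden's J and a sensitivity-targeting policy that returns the most
specific operating point still achieving the target sensitivity (for the
published VOC points, target 0.94 selects the 0.88 threshold).

## Numerical and degenerate-input choices

* Log-normal calibration is closed-form; a residual above 1e-8 (possible
  only through invalid input) is an error. Beta calibration must bring
  both exceedance residuals below 1e-6 or it errors, naming the
  infeasible pair. Anchors with exceedance increasing in threshold are
  rejected as infeasible before any solving.
* Zero denominators in accuracy metrics (an empty class) invalidate that
  metric only, with a warning; an entirely empty table is an error.
* Likelihood ratios require sensitivity and specificity strictly inside
  (0, 1); degenerate tests are rejected with an explicit message, while
  idealised (0/1) performance is still allowed in `test_spec()` for flow
  accounting.
* Youden ties break toward higher specificity, then lower threshold.

## Problem sizes

The test suite and drivers run at desk scale by choice: exact table
reproductions need only the printed counts; calibration-recovery checks
use one 100 000-subject cohort per marker pair (binomial three-standard-
error bands at the anchor thresholds); the odds-update-versus-accounting
identity is checked on a 100-point (sensitivity, specificity, prevalence)
grid; and the leave-one-out equivalence of the CV harness is verified at
n = 30, where the direct loop is cheap.

## Worked example

```{r example}
voc <- test_spec("VOC", 0.94, 0.69)
fit10 <- test_spec("FIT10", 0.54, 0.79)
serial_chain(0.26, list(voc, fit10))
flow_serial(1000, 0.26, voc, fit10)$summary
```

## Limitations

The pipeline evaluates *strategies over supplied performance figures* plus
a distributionally calibrated cohort; it does not model covariate effects,
marker dependence (beyond the optional copula), colonoscopy complication
rates, or costs (the £20-per-test versus £550-per-colonoscopy tariffs
motivate the triage question but no health-economic model is built). The
serial accounting assumes conditional independence of the two tests given
disease status; if the markers were positively dependent within class, the
second test would recover fewer of the first test's misses than the
arithmetic suggests.
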