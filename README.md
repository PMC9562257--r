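# polyptriage

Modelling non-invasive triage for colorectal **polyp surveillance**.
Patients with previously resected polyps are re-scoped at fixed intervals;
most surveillance colonoscopies find no *high-risk finding* (≥2
premalignant polyps including ≥1 advanced polyp, or ≥5 premalignant
polyps). Two non-invasive markers can prioritise that queue: the
quantitative faecal immunochemical test (FIT, µg Hb/g faeces) and a
urinary volatile organic compound (VOC) classifier score in [0, 1]. This
package is for biostatisticians and screening-programme modellers who want
to evaluate such two-test strategies quantitatively.

## What it computes

* **Diagnostic accuracy** — confusion counts at marker cut-offs,
  sensitivity/specificity/PPV/NPV with Wilson or Clopper–Pearson
  intervals, threshold sweeps, empirical ROC operating points and
  trapezoidal AUC (`performance()`, `threshold_sweep()`, `roc_auc()`).
* **Likelihood-ratio (Fagan) calculus** — for a test with sensitivity *s*
  and specificity *c*, LR+ = s/(1−c) and LR− = (1−s)/c update pre-test
  odds to post-test odds. `serial_chain()` follows the rule-out path
  (each test given only to previous negatives); `parallel_combine()`
  combines tests given together, analytically under independence
  (sens = 1−(1−s₁)(1−s₂), spec = c₁c₂) or from supplied empirical figures.
* **Cohort flow** — per-1000-patient accounting of test positives,
  findings detected and missed, colonoscopies required, and the number
  needed to scope (NNS = colonoscopies per finding detected) for
  colonoscopy-for-all, parallel, and serial strategies (`flow_table()`).
* **Cross-validation harness** — seeded balanced k-fold splits, pooled
  out-of-fold scores from an injectable learner (default: logistic score
  model), and ROC-based threshold selection (`cross_validate()`,
  `choose_threshold()`).
* **Calibrated synthetic cohorts** — class-conditional log-normal FIT and
  Beta VOC models fitted to published exceedance anchors, so the whole
  pipeline runs and is tested without patient-level data
  (`calibrate_fit_model()`, `calibrate_voc_model()`, `generate_cohort()`).

## Worked example

Serial triage at surveillance prevalence 0.26, VOC (sens 0.94, spec 0.69
at score threshold 0.88) first, FIT (sens 0.54, spec 0.79 at 10 µg Hb/g)
only in VOC-negatives:

```r
library(polyptriage)
voc   <- test_spec("VOC",   0.94, 0.69)
fit10 <- test_spec("FIT10", 0.54, 0.79)

serial_chain(0.26, list(voc, fit10))
#> Serial rule-out chain, pre-test 26%
#>   VOC negative: 26% -> 3%
#>   FIT10 negative: 3% -> 2%
#>   total probability reduction: 24%

flow_serial(1000, 0.26, voc, fit10)$summary
#>         strategy colonoscopies detected missed number_needed_to_scope nns_exact
#> 1 VOC then FIT10           590      253      7                      2  2.332016
```

A patient negative on both tests carries a 2% residual probability of a
high-risk finding (down 24 points from the 26% prevalence). Per 1000
patients, serial testing needs 590 colonoscopies (474 VOC-positives plus
116 FIT-positives among VOC-negatives) to detect 253 of the 260 findings,
i.e. about 2 colonoscopies per finding detected versus 4 under
scope-everyone — at the price of 7 missed findings per 1000.

The numbered drivers under `analysis/` run the full workflow and write
their tables to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # calibrate models, write cohort CSV
Rscript analysis/02_diagnostic_accuracy.R  # FIT accuracy table + ROC/AUC
Rscript analysis/03_fagan_updates.R        # serial & parallel LR updates
Rscript analysis/04_cohort_flow.R          # per-1000 strategy comparison
Rscript analysis/05_cross_validation.R     # 3-fold CV of the score model
```

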