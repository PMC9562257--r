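test_that("confusion counts partition toy cohorts correctly", {
  co <- data.frame(subject_id = letters[1:4], diseased = c(0, 0, 1, 1),
                   fit_value = c(2, 5, 12, 30), voc_score = 0.5)
  cc <- confusion_at_threshold(co, "fit", 10)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 2L, fp = 0L, fn = 0L, tn = 2L))
  # threshold below every value: everyone positive
  cc0 <- confusion_at_threshold(co, "fit", 1)
  expect_equal(cc0$fn + cc0$tn, 0L)
  # inclusive convention: value == threshold is positive
  eq <- confusion_at_threshold(co, "fit", 30)
  expect_equal(eq$tp, 1L)
  expect_equal(confusion_at_threshold(co, "fit", 30, inclusive = FALSE)$tp, 0L)
})

test_that("confusion counts match a brute-force per-subject tally", {
  co <- make_random_cohort(255, seed = 31)
  for (th in c(0.5, 2, 10, 50)) {
    cc <- confusion_at_threshold(co, "fit", th)
    tally <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in seq_len(nrow(co))) {
      pos <- co$fit_value[i] >= th
      dis <- co$diseased[i] == 1L
      cell <- if (pos && dis) "tp" else if (pos) "fp"
              else if (dis) "fn" else "tn"
      tally[cell] <- tally[cell] + 1L
    }
    expect_equal(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn), tally)
  }
})

test_that("the rank-matched cohort reproduces every published FIT row", {
  co <- make_table2_cohort()
  sweep <- threshold_sweep(co, "fit", table2_cutoffs)
  expect_equal(sweep$tp, table2_tp)
  expect_equal(sweep$tn, table2_tn)
  # monotone: TP and FP non-increasing along the sweep
  expect_true(all(diff(sweep$tp) <= 0))
  expect_true(all(diff(sweep$fp) <= 0))
  expect_true(all(diff(sweep$sensitivity) <= 0))
  expect_true(all(diff(sweep$specificity) >= 0))
  # composition identity: singleton sweep == performance(confusion(...))
  single <- threshold_sweep(co, "fit", 10)
  direct <- performance(confusion_at_threshold(co, "fit", 10), threshold = 10)
  expect_equal(single, direct)
})

test_that("metrics equal their defining count ratios exactly", {
  co <- make_random_cohort(120, seed = 77)
  sweep <- threshold_sweep(co, "fit", c(1, 5, 25))
  for (i in seq_len(nrow(sweep))) {
    r <- sweep[i, ]
    # integer cross-multiplication: the metric is exactly its count ratio
    expect_equal(round(r$sensitivity * (r$tp + r$fn)), r$tp)
    expect_equal(r$sensitivity * (r$tp + r$fn), r$tp, tolerance = 1e-12)
    expect_equal(r$specificity * (r$tn + r$fp), r$tn, tolerance = 1e-12)
    expect_equal(r$ppv * (r$tp + r$fp), r$tp, tolerance = 1e-12)
    expect_equal(r$npv * (r$tn + r$fn), r$tn, tolerance = 1e-12)
    # Bayes consistency: count PPV/NPV equal the prevalence form applied
    # to the unrounded sensitivity/specificity
    pv <- predictive_values(r$sensitivity, r$specificity, r$prevalence)
    expect_equal(r$ppv, pv$ppv, tolerance = 1e-12)
    expect_equal(r$npv, pv$npv, tolerance = 1e-12)
  }
})

test_that("published 10 ug/g row metrics come out at the printed values", {
  perf <- performance(confusion_counts(tp = 37, fp = 39, fn = 31, tn = 148))
  expect_equal(round_half_up(perf$sensitivity, 2), 0.54)
  expect_equal(round_half_up(perf$specificity, 2), 0.79)
  expect_equal(round_half_up(perf$npv, 2), 0.83)
  # the table's predictive values follow the prevalence form applied to
  # the displayed (2 dp) sensitivity/specificity
  pv <- predictive_values(0.54, 0.79, 0.26)
  expect_equal(round_half_up(pv$ppv, 2), 0.47)
  expect_equal(round_half_up(pv$npv, 2), 0.83)
  # 7 ug/g row
  perf7 <- performance(confusion_counts(tp = 37, fp = 47, fn = 31, tn = 140))
  expect_equal(round_half_up(perf7$sensitivity, 2), 0.54)
  expect_equal(round_half_up(perf7$specificity, 2), 0.75)
  # degenerate classifier (its empty PPV denominator warns, tested below)
  perf0 <- suppressWarnings(
    performance(confusion_counts(tp = 0, fp = 0, fn = 10, tn = 10)))
  expect_equal(perf0$sensitivity, 0)
  expect_equal(perf0$specificity, 1)
})

test_that("interval methods agree with their base-R oracles", {
  cases <- list(c(37, 68), c(148, 187), c(1, 20), c(19, 20))
  for (xn in cases) {
    x <- xn[1]; n <- xn[2]
    wilson <- ci_proportion(x, n, "wilson")
    oracle <- prop.test(x, n, correct = FALSE)$conf.int
    expect_equal(unname(wilson), as.numeric(oracle), tolerance = 1e-10)
    cp <- ci_proportion(x, n, "clopper_pearson")
    oracle2 <- binom.test(x, n)$conf.int
    expect_equal(unname(cp), as.numeric(oracle2), tolerance = 1e-10)
  }
  # boundary cases stay inside [0, 1]
  expect_equal(ci_proportion(0, 10, "clopper_pearson")[["lo"]], 0)
  expect_equal(ci_proportion(10, 10, "clopper_pearson")[["hi"]], 1)
})

test_that("zero denominators degrade one metric, not the whole row", {
  expect_warning(p <- performance(confusion_counts(0, 0, 5, 5)), "PPV")
  expect_true(is.na(p$ppv))
  expect_equal(p$specificity, 1)
  expect_error(performance(confusion_counts(0, 0, 0, 0)), "empty")
})

test_that("trapezoidal AUC has its closed-form fixed points", {
  # chance diagonal from anchors alone
  expect_equal(roc_auc(data.frame(fpr = 0.5, tpr = 0.5)), 0.5)
  # perfect classifier corner
  expect_equal(roc_auc(data.frame(fpr = 0, tpr = 1)), 1.0)
  expect_error(roc_auc(data.frame(fpr = -0.1, tpr = 0.5)), "unit square")
  expect_error(roc_auc(data.frame(fpr = numeric(), tpr = numeric())))
})

test_that("AUC is invariant under permutation of operating points", {
  pts <- data.frame(fpr = c(0.1, 0.4, 0.7, 0.4), tpr = c(0.5, 0.8, 0.9, 0.8))
  base <- roc_auc(pts)
  for (i in 1:5) {
    perm <- pts[with_test_seed(i, sample(nrow(pts))), ]
    expect_equal(roc_auc(perm), base)
  }
})

test_that("the published FIT operating points integrate to AUC 0.67", {
  pts <- data.frame(fpr = 1 - table2_tn / 187, tpr = table2_tp / 68)
  expect_equal(round_half_up(roc_auc(pts), 2), 0.67)
  # and the same points derived through roc_points on the rank cohort
  co <- make_table2_cohort()
  pts2 <- roc_points(co, "fit", table2_cutoffs)
  expect_equal(pts2$fpr, pts$fpr)
  expect_equal(pts2$tpr, pts$tpr)
})

test_that("roc_points defaults to the full empirical curve", {
  co <- make_random_cohort(60, seed = 5)
  pts <- roc_points(co, "voc")
  expect_equal(nrow(pts), length(unique(co$voc_score)))
  expect_true(all(diff(pts$fpr) <= 0))  # thresholds ascending -> fpr falls
  skip_if_not_installed("pROC")
  oracle <- as.numeric(pROC::auc(pROC::roc(
    co$diseased, co$voc_score, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(pts), oracle, tolerance = 1e-10)
})
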