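test_that("fold assignment is balanced, deterministic and a partition", {
  ids <- sprintf("S%03d", 1:255)
  f <- assign_folds(ids, k = 3, seed = 1)
  expect_equal(unname(table(f)), rep(85L, 3), ignore_attr = TRUE)
  expect_identical(sort(names(f)), sort(ids))
  expect_identical(f, assign_folds(ids, k = 3, seed = 1))
  expect_false(identical(f, assign_folds(ids, k = 3, seed = 2)))
  # remainder handling
  sizes <- sort(as.integer(table(assign_folds(letters[1:7], 3, seed = 5))))
  expect_equal(sizes, c(2L, 2L, 3L))
  expect_error(assign_folds(letters[1:2], k = 3, seed = 1), "at least")
  expect_error(assign_folds(c("a", "a", "b"), k = 2, seed = 1), "unique")
  # input order does not matter
  expect_identical(assign_folds(rev(ids), k = 3, seed = 1), f)
})

test_that("stratified assignment keeps both classes in every fold", {
  ids <- sprintf("S%03d", 1:60)
  cls <- rep(c(1L, 0L), c(9, 51))
  f <- assign_folds(ids, k = 3, seed = 4, stratify_by = cls)
  split_cls <- split(cls[order(ids)][order(names(f))], f)
  for (s in split_cls) expect_true(all(c(0L, 1L) %in% s))
})

test_that("identity learner pools to exactly the raw-score ROC", {
  co <- generate_cohort(generator_spec(n_subjects = 150, seed = 12), 0.3)
  cv <- cross_validate(co, k = 3, seed = 7, learner = learner_identity())
  expect_equal(sort(cv$scores$score), sort(co$voc_score))
  direct <- roc_points(co, "voc")
  expect_equal(cv$points, direct)
  expect_equal(cv$auc, roc_auc(direct))
})

test_that("every subject is scored once, by a model that never saw it", {
  co <- generate_cohort(generator_spec(n_subjects = 90, seed = 3), 0.3)
  cv <- cross_validate(co, k = 3, seed = 11)
  expect_equal(sort(cv$scores$subject_id), sort(co$subject_id))
  expect_false(any(is.na(cv$scores$score)))
  # no leakage: recompute each fold's scores from scratch on the
  # complementary training set and compare
  co_sorted <- co[order(co$subject_id), ]
  learner <- learner_logistic("voc_score")
  for (f in 1:3) {
    held <- cv$folds == f
    again <- learner(co_sorted[!held, ], co_sorted[held, ])
    expect_equal(cv$scores$score[held], again, tolerance = 1e-12)
  }
})

test_that("k = n cross-validation equals a direct leave-one-out loop", {
  n <- 24
  co <- generate_cohort(generator_spec(n_subjects = n, seed = 19), 0.4)
  cv <- cross_validate(co, k = n, seed = 2)
  co_sorted <- co[order(co$subject_id), ]
  loo <- vapply(seq_len(n), function(i) {
    fit <- glm(diseased ~ voc_score, binomial(), data = co_sorted[-i, ])
    as.numeric(predict(fit, co_sorted[i, , drop = FALSE],
                       type = "response"))
  }, numeric(1))
  # folds are singletons, so oof scores must equal the LOO loop per subject
  expect_equal(unname(table(cv$folds)), rep(1L, n), ignore_attr = TRUE)
  scores_by_id <- cv$scores$score
  expect_equal(scores_by_id, loo, tolerance = 1e-10)
  # pooled confusion at a threshold equals the loop's tally
  th <- 0.5
  cc <- confusion_at_threshold(
    data.frame(subject_id = co_sorted$subject_id,
               diseased = co_sorted$diseased,
               fit_value = 0, voc_score = scores_by_id), "voc", th)
  expect_equal(cc$tp, sum(loo >= th & co_sorted$diseased == 1))
  expect_equal(cc$tn, sum(loo < th & co_sorted$diseased == 0))
})

test_that("single-class training folds trigger stratified reassignment", {
  # a lone case guarantees some training set sees one class only
  co <- data.frame(subject_id = sprintf("S%02d", 1:30),
                   diseased = rep(c(1L, 0L), c(1, 29)),
                   fit_value = 1,
                   voc_score = with_test_seed(6, runif(30)))
  w <- capture_warnings(cv <- cross_validate(co, k = 3, seed = 8))
  expect_true(any(grepl("single-class", w)))
  expect_false(any(is.na(cv$scores$score)))
})

test_that("logistic out-of-fold AUC tracks the population score AUC", {
  # population AUC of the VOC score by quadrature over the calibrated
  # class densities: P(S_dis > S_hea) = int f_dis(s) F_hea(s) ds
  tg <- calibration_targets()
  md <- calibrate_voc_model(tg$voc_diseased$threshold,
                            tg$voc_diseased$exceedance)
  mh <- calibrate_voc_model(tg$voc_healthy$threshold,
                            tg$voc_healthy$exceedance)
  pop_auc <- integrate(function(s)
    dbeta(s, md$shape1, md$shape2) * pbeta(s, mh$shape1, mh$shape2),
    0, 1, rel.tol = 1e-10)$value
  co <- generate_cohort(generator_spec(n_subjects = 255, seed = 23), 0.26)
  cv <- cross_validate(co, features = "voc_score", k = 3, seed = 14)
  # a monotone score model preserves the score's discrimination, up to
  # Monte-Carlo spread at n = 255 (3 x Hanley-McNeil SE is about 0.08)
  expect_lt(abs(cv$auc - pop_auc), 0.08)
})

test_that("threshold policies match their exhaustive-scan oracles", {
  co <- make_random_cohort(80, seed = 41)
  pts <- roc_points(co, "voc")
  # youden by brute force over all cutpoints
  j <- pts$tpr - pts$fpr
  oracle <- pts$threshold[which.max(j)]
  chosen <- choose_threshold(pts, "youden")
  expect_equal(pts$tpr[pts$threshold == chosen] -
                 pts$fpr[pts$threshold == chosen], max(j))
  expect_equal(chosen, oracle)
  # perfectly separated scores reach the (fpr 0, tpr 1) corner
  sep <- data.frame(subject_id = letters[1:6],
                    diseased = rep(c(0L, 1L), each = 3),
                    fit_value = 0,
                    voc_score = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  th <- choose_threshold(roc_points(sep, "voc"), "youden")
  cc <- confusion_at_threshold(sep, "voc", th)
  expect_equal(c(cc$fp, cc$fn), c(0L, 0L))
})

test_that("the sensitivity-targeting policy picks the published threshold", {
  expect_equal(
    choose_threshold(voc_table3, "target_sensitivity", target = 0.94), 0.88)
  expect_error(
    choose_threshold(voc_table3, "target_sensitivity", target = 0.999),
    "maximum attainable")
})
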