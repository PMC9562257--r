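#' Seeded balanced fold assignment
#'
#' Randomises subjects into `k` folds whose sizes differ by at most one.
#' By default a plain seeded shuffle; with `stratify_by` the shuffle and
#' round-robin allocation happen within each stratum, guaranteeing every
#' fold sees both classes whenever each class has at least `k` members.
#' Deterministic in (ids, k, seed): the ids are sorted before shuffling, so
#' the input order does not matter.
#'
#' @param subject_ids character vector of unique ids.
#' @param k number of folds (>= 2, <= number of subjects).
#' @param seed integer seed.
#' @param stratify_by optional vector (same length/order as `subject_ids`)
#'   of class labels to stratify on.
#' @return Integer vector of fold labels in 1..k, named by subject id,
#'   in sorted id order.
#' @export
#' @examples
#' table(assign_folds(sprintf("S%03d", 1:255), k = 3, seed = 1))
assign_folds <- function(subject_ids, k, seed, stratify_by = NULL) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop_arg("subject ids must be unique")
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop_arg("k must be an integer >= 2")
  if (n < k) stop_arg("need at least k = ", k, " subjects, got ", n)
  ord <- order(subject_ids)
  ids <- subject_ids[ord]
  strata <- if (is.null(stratify_by)) rep(1L, n) else stratify_by[ord]
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      idx <- which(strata == s)
      shuffled <- idx[sample.int(length(idx))]
      # round-robin over folds, continuing from where the last stratum
      # stopped so overall sizes stay balanced
      folds[shuffled] <- ((offset + seq_along(shuffled) - 1L) %% k) + 1L
      offset <- (offset + length(shuffled)) %% k
    }
  })
  stats::setNames(folds, ids)
}

#' Logistic out-of-fold scorer
#'
#' Returns a learner for [cross_validate()]: a logistic regression of
#' high-risk status on the given feature columns, scoring held-out
#' subjects by predicted probability. This is the package's stand-in for
#' a pattern-recognition classifier whose architecture is not published;
#' any function with the same signature can be injected instead.
#'
#' @param features character vector of cohort columns, e.g. `"voc_score"`
#'   or `c("voc_score", "fit_value")`.
#' @return A function `(train, test) -> numeric scores in [0, 1]`.
#' @export
learner_logistic <- function(features = "voc_score") {
  force(features)
  function(train, test) {
    fml <- stats::as.formula(
      paste("diseased ~", paste(features, collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = train)
    as.numeric(stats::predict(fit, newdata = test, type = "response"))
  }
}

#' Identity scorer: pass the VOC score through untrained
#'
#' Useful as a baseline and for testing: pooled out-of-fold scores are then
#' exactly the raw scores, so the pooled ROC must equal the ROC on the raw
#' data.
#'
#' @return A learner function for [cross_validate()].
#' @export
learner_identity <- function() {
  function(train, test) test$voc_score
}

#' k-fold cross-validation with pooled out-of-fold scores
#'
#' Randomises the cohort into `k` folds, trains the learner on each set of
#' k-1 folds and scores the held-out fold, so every subject is scored
#' exactly once by a model that never saw it. The out-of-fold scores are
#' pooled into a single empirical ROC (one AUC for the whole cohort,
#' rather than averaging per-fold curves). If any training set would
#' contain a single class, folds are reassigned with stratification and a
#' warning.
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param features feature columns passed to the default learner.
#' @param k number of folds (default 3).
#' @param seed integer seed for the fold shuffle.
#' @param learner a function `(train, test) -> scores in [0, 1]`; default
#'   [learner_logistic()] on `features`.
#' @return List of class `"cv_result"`: `scores` (data frame `subject_id`,
#'   `diseased`, `fold`, `score`), `folds`, `k`, `seed`, `points` (pooled
#'   ROC operating points at every distinct score), and `auc`.
#' @export
#' @examples
#' cohort <- generate_cohort(generator_spec(n_subjects = 120, seed = 7))
#' cv <- cross_validate(cohort, k = 3, seed = 42)
#' cv$auc
cross_validate <- function(cohort, features = "voc_score", k = 3, seed = 1,
                           learner = NULL) {
  validate_cohort(cohort)
  if (is.null(learner)) learner <- learner_logistic(features)
  folds <- assign_folds(cohort$subject_id, k = k, seed = seed)
  cohort <- cohort[order(cohort$subject_id), ]
  bad <- vapply(seq_len(k), function(f) {
    tr <- cohort$diseased[folds != f]
    length(unique(tr)) < 2L
  }, logical(1))
  if (any(bad)) {
    warning("single-class training fold; reassigning with stratification",
            call. = FALSE)
    folds <- assign_folds(cohort$subject_id, k = k, seed = seed,
                          stratify_by = cohort$diseased)
  }
  score <- rep(NA_real_, nrow(cohort))
  for (f in seq_len(k)) {
    held <- folds == f
    score[held] <- learner(cohort[!held, , drop = FALSE],
                           cohort[held, , drop = FALSE])
  }
  if (any(!is.finite(score)) || any(score < 0 | score > 1))
    stop_arg("learner must produce finite scores in [0, 1]")
  scored <- data.frame(subject_id = cohort$subject_id,
                       diseased = cohort$diseased,
                       fold = as.integer(folds),
                       score = score, stringsAsFactors = FALSE)
  pooled <- scored
  names(pooled)[names(pooled) == "score"] <- "voc_score"
  pooled$fit_value <- 0
  points <- roc_points(pooled, "voc")
  structure(list(scores = scored, folds = folds, k = as.integer(k),
                 seed = as.integer(seed), points = points,
                 auc = roc_auc(points)),
            class = "cv_result")
}

#' Choose an operating threshold from pooled ROC points
#'
#' `policy = "youden"` maximises Youden's J = tpr - fpr over the operating
#' points (ties broken toward higher specificity, then lower threshold).
#' `policy = "target_sensitivity"` returns, among operating points whose
#' sensitivity is at least `target`, the one with the highest specificity
#' (ties toward the lower threshold); because sensitivity falls as the
#' threshold rises, this is the most specific cut-off still meeting the
#' sensitivity requirement. Errors if no point reaches the target, naming
#' the maximum attainable sensitivity.
#'
#' @param x a `"cv_result"` or a data frame of operating points with
#'   columns `threshold`, `fpr`, `tpr`.
#' @param policy `"youden"` or `"target_sensitivity"`.
#' @param target required minimum sensitivity for
#'   `policy = "target_sensitivity"`.
#' @return The chosen threshold (scalar).
#' @export
#' @examples
#' pts <- data.frame(threshold = c(0.78, 0.81, 0.88, 0.94, 0.95),
#'                   tpr = c(0.99, 0.98, 0.94, 0.66, 0.43),
#'                   fpr = 1 - c(0.48, 0.54, 0.69, 0.76, 0.77))
#' choose_threshold(pts, "target_sensitivity", target = 0.94)
choose_threshold <- function(x, policy = c("youden", "target_sensitivity"),
                             target = NULL) {
  policy <- match.arg(policy)
  points <- if (inherits(x, "cv_result")) x$points else x
  if (!is.data.frame(points) ||
      !all(c("threshold", "fpr", "tpr") %in% names(points)) ||
      nrow(points) == 0L)
    stop_arg("need pooled operating points with threshold, fpr, tpr")
  if (policy == "youden") {
    j <- points$tpr - points$fpr
    best <- which(j == max(j))
    best <- best[order(points$fpr[best], points$threshold[best])][1L]
    points$threshold[best]
  } else {
    if (!is_prob(target))
      stop_arg("target_sensitivity policy needs target in [0, 1]")
    ok <- which(points$tpr >= target)
    if (length(ok) == 0L)
      stop_arg("no threshold reaches sensitivity ", target,
               "; maximum attainable is ", signif(max(points$tpr), 4))
    best <- ok[order(points$fpr[ok], points$threshold[ok])][1L]
    points$threshold[best]
  }
}
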