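#' Confusion counts at a marker threshold
#'
#' Dichotomises one marker at a cut-off and tallies the 2x2 table against
#' the high-risk-finding status. A subject is test-positive iff the marker
#' value is `>=` the threshold (`inclusive = TRUE`, the default, matching
#' cut-off language for an assay with a detection limit); set
#' `inclusive = FALSE` for strict `>`.
#'
#' @param cohort cohort data frame (see [generate_cohort()]).
#' @param marker `"fit"` or `"voc"`.
#' @param threshold finite cut-off in marker units.
#' @param inclusive logical; positive iff value >= threshold when `TRUE`.
#' @return A list of class `"confusion_counts"` with integer `tp`, `fp`,
#'   `fn`, `tn`; the four counts partition the cohort.
#' @export
#' @examples
#' cohort <- data.frame(subject_id = letters[1:4], diseased = c(0, 0, 1, 1),
#'                      fit_value = c(2, 5, 12, 30), voc_score = 0.5)
#' confusion_at_threshold(cohort, "fit", 10)
confusion_at_threshold <- function(cohort, marker = c("fit", "voc"),
                                   threshold, inclusive = TRUE) {
  validate_cohort(cohort)
  marker <- match.arg(marker)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold))
    stop_arg("threshold must be a single finite number")
  value <- if (marker == "fit") cohort$fit_value else cohort$voc_score
  pos <- if (inclusive) value >= threshold else value > threshold
  dis <- cohort$diseased == 1L
  confusion_counts(tp = sum(pos & dis), fp = sum(pos & !dis),
                   fn = sum(!pos & dis), tn = sum(!pos & !dis))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells)))
    stop_arg("confusion cells must be non-negative integers")
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3],
                 tn = cells[4]), class = "confusion_counts")
}

#' Confidence interval for a binomial proportion
#'
#' Wilson score interval (default) or exact Clopper-Pearson via the Beta
#' quantile. Degenerate `n = 0` gives an NA interval.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param level confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
ci_proportion <- function(x, n, method = c("wilson", "clopper_pearson"),
                          level = 0.95) {
  method <- match.arg(method)
  if (n == 0) return(c(lo = NA_real_, hi = NA_real_))
  if (method == "wilson") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(lo = max(0, centre - half), hi = min(1, centre + half))
  } else {
    alpha <- 1 - level
    lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    c(lo = lo, hi = hi)
  }
}

#' Prevalence-form predictive values
#'
#' Positive and negative predictive values from sensitivity, specificity
#' and prevalence via Bayes' theorem:
#' PPV = sens*pi / (sens*pi + (1-spec)(1-pi)) and
#' NPV = spec(1-pi) / (spec(1-pi) + (1-sens)pi).
#' Useful for carrying accuracy estimates to a different prevalence, and
#' for reproducing tables whose predictive values were derived from the
#' displayed (rounded) sensitivity/specificity rather than raw counts.
#'
#' @param sensitivity,specificity,prevalence probabilities (vectorised,
#'   recycled to a common length).
#' @return List with `ppv` and `npv`.
#' @export
#' @examples
#' predictive_values(0.54, 0.79, 0.26)
predictive_values <- function(sensitivity, specificity, prevalence) {
  ok <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 1)
  if (!ok(sensitivity) || !ok(specificity) || !ok(prevalence))
    stop_arg("sensitivity, specificity and prevalence must lie in [0, 1]")
  p <- prevalence
  list(ppv = sensitivity * p / (sensitivity * p +
                                  (1 - specificity) * (1 - p)),
       npv = specificity * (1 - p) / (specificity * (1 - p) +
                                        (1 - sensitivity) * p))
}

#' Accuracy metrics with interval estimates from a confusion table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp) and NPV
#' tn/(tn+fn), each with a binomial interval over its own denominator, plus
#' the prevalence-form PPV/NPV (columns `ppv_bayes`, `npv_bayes`) computed
#' from the unrounded sensitivity/specificity via [predictive_values()]. A
#' zero denominator leaves that metric `NA` with a warning rather than
#' failing the whole row.
#'
#' @param counts a `"confusion_counts"` object.
#' @param ci_method `"wilson"` (default) or `"clopper_pearson"`.
#' @param level confidence level.
#' @param threshold optional cut-off to carry along in the output row.
#' @return One-row data frame: `threshold`, the four counts, `n_diseased`,
#'   `n_healthy`, `prevalence`, and point/lo/hi columns per metric.
#' @export
#' @examples
#' performance(confusion_counts(tp = 37, fp = 39, fn = 31, tn = 148))
performance <- function(counts, ci_method = c("wilson", "clopper_pearson"),
                        level = 0.95, threshold = NA_real_) {
  if (!inherits(counts, "confusion_counts"))
    stop_arg("counts must be a confusion_counts object")
  ci_method <- match.arg(ci_method)
  n_dis <- counts$tp + counts$fn
  n_hea <- counts$tn + counts$fp
  n <- n_dis + n_hea
  if (n == 0) stop_arg("empty confusion table")
  ratio <- function(x, d, what) {
    if (d == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(c(NA_real_, NA_real_, NA_real_))
    }
    c(x / d, ci_proportion(x, d, ci_method, level))
  }
  sens <- ratio(counts$tp, n_dis, "sensitivity")
  spec <- ratio(counts$tn, n_hea, "specificity")
  ppv  <- ratio(counts$tp, counts$tp + counts$fp, "PPV")
  npv  <- ratio(counts$tn, counts$tn + counts$fn, "NPV")
  prev <- n_dis / n
  bayes <- if (is.na(sens[1]) || is.na(spec[1]))
    list(ppv = NA_real_, npv = NA_real_)
  else predictive_values(sens[1], spec[1], prev)
  data.frame(threshold = threshold,
             tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
             n_diseased = n_dis, n_healthy = n_hea, prevalence = prev,
             sensitivity = sens[1], sens_lo = sens[2], sens_hi = sens[3],
             specificity = spec[1], spec_lo = spec[2], spec_hi = spec[3],
             ppv = ppv[1], ppv_lo = ppv[2], ppv_hi = ppv[3],
             npv = npv[1], npv_lo = npv[2], npv_hi = npv[3],
             ppv_bayes = bayes$ppv, npv_bayes = bayes$npv)
}

#' Accuracy metrics over an increasing ladder of cut-offs
#'
#' Applies [confusion_at_threshold()] and [performance()] at each cut-off.
#' With the inclusive positivity convention, true-positive and
#' false-positive counts are non-increasing along the sweep, so sensitivity
#' is non-increasing and specificity non-decreasing.
#'
#' @inheritParams confusion_at_threshold
#' @param thresholds strictly increasing numeric vector of cut-offs.
#' @inheritParams performance
#' @return Data frame with one [performance()] row per threshold.
#' @export
threshold_sweep <- function(cohort, marker = c("fit", "voc"), thresholds,
                            ci_method = c("wilson", "clopper_pearson"),
                            level = 0.95, inclusive = TRUE) {
  marker <- match.arg(marker)
  ci_method <- match.arg(ci_method)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop_arg("thresholds must be strictly increasing")
  rows <- lapply(thresholds, function(th)
    performance(confusion_at_threshold(cohort, marker, th, inclusive),
                ci_method = ci_method, level = level, threshold = th))
  do.call(rbind, rows)
}

#' Empirical ROC operating points
#'
#' One (fpr, tpr) vertex per cut-off; by default the cut-offs are every
#' distinct marker value, giving the full empirical ROC.
#'
#' @inheritParams confusion_at_threshold
#' @param thresholds cut-offs; default all distinct marker values.
#' @return Data frame `threshold`, `fpr` (1 - specificity), `tpr`
#'   (sensitivity).
#' @export
roc_points <- function(cohort, marker = c("fit", "voc"), thresholds = NULL,
                       inclusive = TRUE) {
  validate_cohort(cohort)
  marker <- match.arg(marker)
  value <- if (marker == "fit") cohort$fit_value else cohort$voc_score
  if (is.null(thresholds)) thresholds <- sort(unique(value))
  dis <- cohort$diseased == 1L
  n_dis <- sum(dis); n_hea <- sum(!dis)
  if (n_dis == 0 || n_hea == 0)
    stop_arg("ROC needs at least one subject in each class")
  pts <- vapply(thresholds, function(th) {
    pos <- if (inclusive) value >= th else value > th
    c(sum(pos & !dis) / n_hea, sum(pos & dis) / n_dis)
  }, numeric(2))
  data.frame(threshold = thresholds, fpr = pts[1, ], tpr = pts[2, ])
}

#' Trapezoidal area under empirical ROC operating points
#'
#' Sorts the operating points by false-positive rate (ties broken by
#' true-positive rate ascending), optionally appends the (0,0) and (1,1)
#' anchors, and integrates by the trapezoid rule. The result is invariant
#' to the input ordering.
#'
#' @param points data frame with columns `fpr` and `tpr`, all in \[0, 1\].
#' @param anchored append the chance anchors before integrating
#'   (default `TRUE`).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(data.frame(fpr = 0, tpr = 1))   # perfect corner -> 1
roc_auc <- function(points, anchored = TRUE) {
  if (!is.data.frame(points) || !all(c("fpr", "tpr") %in% names(points)))
    stop_arg("points must be a data frame with fpr and tpr columns")
  if (nrow(points) < 1L) stop_arg("at least one operating point is required")
  if (any(!is.finite(points$fpr)) || any(!is.finite(points$tpr)) ||
      any(points$fpr < 0 | points$fpr > 1 | points$tpr < 0 | points$tpr > 1))
    stop_arg("operating points must lie in the unit square")
  x <- points$fpr; y <- points$tpr
  if (anchored) { x <- c(0, x, 1); y <- c(0, y, 1) }
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              status = c("high-risk", "low-risk")))
  print(m)
  invisible(x)
}
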