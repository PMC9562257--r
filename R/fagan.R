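#' A diagnostic test as an assumed (sensitivity, specificity) pair
#'
#' Performance figures decoupled from any cohort, as used for
#' likelihood-ratio updates and cohort-flow accounting. Values of exactly
#' 0 or 1 are accepted here (they arise for idealised tests), but
#' [likelihood_ratios()] requires both in (0, 1).
#'
#' @param name label for reports.
#' @param sensitivity,specificity probabilities in \[0, 1\].
#' @return List of class `"test_spec"`.
#' @export
#' @examples
#' voc <- test_spec("VOC", 0.94, 0.69)
#' fit <- test_spec("FIT10", 0.54, 0.79)
test_spec <- function(name, sensitivity, specificity) {
  if (!is.character(name) || length(name) != 1L)
    stop_arg("name must be a single string")
  if (!is_prob(sensitivity) || !is_prob(specificity))
    stop_arg("sensitivity and specificity must lie in [0, 1]")
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity), class = "test_spec")
}

#' Likelihood ratios of a test
#'
#' LR+ = sens / (1 - spec) multiplies the pre-test odds after a positive
#' result; LR- = (1 - sens) / spec after a negative result. For an
#' informative test (sens + spec > 1), LR+ > 1 > LR-.
#'
#' @param test a [test_spec()] with both figures strictly inside (0, 1).
#' @return List with `lr_positive` and `lr_negative`.
#' @export
#' @examples
#' likelihood_ratios(test_spec("VOC", 0.94, 0.69))
likelihood_ratios <- function(test) {
  stopifnot(inherits(test, "test_spec"))
  s <- test$sensitivity; c <- test$specificity
  if (s <= 0 || s >= 1 || c <= 0 || c >= 1)
    stop_arg("likelihood ratios require sensitivity and specificity ",
             "strictly in (0, 1); test '", test$name, "' has sens = ", s,
             ", spec = ", c, " (LR would be 0, infinite or undefined)")
  list(lr_positive = s / (1 - c), lr_negative = (1 - s) / c)
}

odds <- function(p) p / (1 - p)
prob <- function(o) o / (1 + o)

#' Post-test probabilities by the likelihood-ratio (Fagan) update
#'
#' The numerical content of Fagan's nomogram: convert the pre-test
#' probability to odds, multiply by LR+ or LR-, convert back. All
#' propagation is in full precision; use [format_percent()] (or
#' `print()`) for the whole-percent display convention. Pre-test
#' probabilities of exactly 0 or 1 are fixed points and are returned
#' unchanged.
#'
#' @param pre_test_prob probability of disease before testing.
#' @param test a [test_spec()].
#' @return List of class `"fagan_update"`: `test`, `pre_test_prob`,
#'   `lr_positive`, `lr_negative`, `post_test_prob_positive`,
#'   `post_test_prob_negative`, and `probability_reduction`
#'   (pre minus post-negative).
#' @export
#' @examples
#' fagan_update(0.26, test_spec("VOC", 0.94, 0.69))
fagan_update <- function(pre_test_prob, test) {
  stopifnot(inherits(test, "test_spec"))
  if (!is_prob(pre_test_prob))
    stop_arg("pre_test_prob must lie in [0, 1]")
  if (pre_test_prob %in% c(0, 1)) {
    post_pos <- post_neg <- pre_test_prob
    lr <- list(lr_positive = NA_real_, lr_negative = NA_real_)
  } else {
    lr <- likelihood_ratios(test)
    pre_odds <- odds(pre_test_prob)
    post_pos <- prob(pre_odds * lr$lr_positive)
    post_neg <- prob(pre_odds * lr$lr_negative)
  }
  structure(list(test = test,
                 pre_test_prob = pre_test_prob,
                 lr_positive = lr$lr_positive,
                 lr_negative = lr$lr_negative,
                 post_test_prob_positive = post_pos,
                 post_test_prob_negative = post_neg,
                 probability_reduction = pre_test_prob - post_neg),
            class = "fagan_update")
}

#' Serial rule-out chain of likelihood-ratio updates
#'
#' Applies the tests in order along the all-negative path: each test is
#' given only to patients negative on all previous tests, so update i+1
#' takes update i's post-test probability after a negative result as its
#' pre-test probability. This is the rule-out triage use of serial
#' testing; positive patients leave the chain for colonoscopy (accounted
#' for in [flow_serial()], not by further updates).
#'
#' @param pre_test_prob initial disease probability (e.g. the surveillance
#'   prevalence, 0.26).
#' @param tests list of [test_spec()] objects, first test first.
#' @param display_rounded_propagation if `TRUE`, each stage's pre-test
#'   probability is first rounded to a whole percent, mimicking reading
#'   intermediate values off a printed nomogram. Default `FALSE`
#'   (full-precision propagation).
#' @return List of class `"fagan_chain"`: `updates` (one
#'   [fagan_update()] per test), `pre_test_prob`,
#'   `final_post_negative`, and `total_probability_reduction`
#'   (initial pre minus final post-negative).
#' @export
#' @examples
#' serial_chain(0.26, list(test_spec("VOC", 0.94, 0.69),
#'                         test_spec("FIT10", 0.54, 0.79)))
serial_chain <- function(pre_test_prob, tests,
                         display_rounded_propagation = FALSE) {
  if (!is.list(tests) || length(tests) == 0L)
    stop_arg("tests must be a non-empty list of test_spec objects")
  if (inherits(tests, "test_spec")) tests <- list(tests)
  updates <- vector("list", length(tests))
  p <- pre_test_prob
  for (i in seq_along(tests)) {
    if (display_rounded_propagation && i > 1L)
      p <- round_half_up(p, 2)
    updates[[i]] <- fagan_update(p, tests[[i]])
    p <- updates[[i]]$post_test_prob_negative
  }
  structure(list(updates = updates,
                 pre_test_prob = pre_test_prob,
                 final_post_negative = p,
                 total_probability_reduction = pre_test_prob - p),
            class = "fagan_chain")
}

#' Combine two tests given in parallel
#'
#' Under parallel testing both tests are given together and disease is
#' called absent only if both are negative. `mode = "independence"`
#' combines analytically assuming conditional independence:
#' sens = 1 - (1 - s1)(1 - s2), spec = c1 * c2. `mode = "supplied"` returns
#' a caller-provided empirical pair instead — appropriate when the combined
#' classifier was fit jointly (e.g. a score model retrained on both
#' markers), in which case the independence product does not apply; the
#' published combined VOC+FIT figures (0.97, 0.11) are of this kind.
#'
#' @param test1,test2 [test_spec()] objects.
#' @param mode `"independence"` or `"supplied"`.
#' @param supplied for `mode = "supplied"`, numeric
#'   `c(sensitivity, specificity)` of the combined test.
#' @param name label for the combined test.
#' @return A [test_spec()] for the combination.
#' @export
#' @examples
#' parallel_combine(test_spec("VOC", 0.94, 0.69),
#'                  test_spec("FIT10", 0.54, 0.79))
parallel_combine <- function(test1, test2,
                             mode = c("independence", "supplied"),
                             supplied = NULL,
                             name = NULL) {
  stopifnot(inherits(test1, "test_spec"), inherits(test2, "test_spec"))
  mode <- match.arg(mode)
  if (is.null(name))
    name <- paste0(test1$name, "||", test2$name)
  if (mode == "independence") {
    test_spec(name,
              sensitivity = 1 - (1 - test1$sensitivity) *
                (1 - test2$sensitivity),
              specificity = test1$specificity * test2$specificity)
  } else {
    if (is.null(supplied) || length(supplied) != 2L)
      stop_arg("mode = 'supplied' needs supplied = c(sensitivity, ",
               "specificity)")
    test_spec(name, supplied[1], supplied[2])
  }
}

#' Format a probability as a whole percent
#'
#' Round-half-away-from-zero display convention used for nomogram figures.
#'
#' @param p probability (vectorised).
#' @param digits decimal places of the percentage (default 0).
#' @return Numeric percentage(s).
#' @export
#' @examples
#' format_percent(0.5158)  # 52
format_percent <- function(p, digits = 0) {
  round_half_up(100 * p, digits)
}

#' @export
print.fagan_update <- function(x, ...) {
  cat(sprintf(
    "Fagan update for %s (sens %.2f, spec %.2f)\n", x$test$name,
    x$test$sensitivity, x$test$specificity))
  cat(sprintf("  pre-test probability: %d%%\n",
              format_percent(x$pre_test_prob)))
  cat(sprintf("  LR+ %.3f -> post-test (positive): %d%%\n",
              x$lr_positive, format_percent(x$post_test_prob_positive)))
  cat(sprintf("  LR- %.3f -> post-test (negative): %d%%\n",
              x$lr_negative, format_percent(x$post_test_prob_negative)))
  cat(sprintf("  probability reduction: %d%%\n",
              format_percent(x$probability_reduction)))
  invisible(x)
}

#' @export
print.fagan_chain <- function(x, ...) {
  cat(sprintf("Serial rule-out chain, pre-test %d%%\n",
              format_percent(x$pre_test_prob)))
  for (u in x$updates)
    cat(sprintf("  %s negative: %d%% -> %d%%\n", u$test$name,
                format_percent(u$pre_test_prob),
                format_percent(u$post_test_prob_negative)))
  cat(sprintf("  total probability reduction: %d%%\n",
              format_percent(x$total_probability_reduction)))
  invisible(x)
}
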