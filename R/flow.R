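#' Per-1000-patient accounting of a single-stage testing strategy
#'
#' Expected-frequency bookkeeping for giving one test to a cohort of `n`
#' patients at the stated prevalence: how many test positive, how many
#' high-risk findings sit among the positives (detected, since every
#' positive proceeds to colonoscopy, treated as a perfect gold standard)
#' and among the negatives (missed). Each reported cell is rounded half
#' away from zero to a whole patient; the unrounded expectations are
#' retained in `*_raw` columns. Negatives are defined as `n` minus the
#' rounded positives so the single-stage row always partitions the cohort.
#'
#' @param n cohort size (default 1000).
#' @param prevalence probability of a high-risk finding.
#' @param test a [test_spec()].
#' @param label strategy label (defaults to the test name).
#' @return One-row data frame of class `"cohort_flow"`: `strategy`,
#'   `sensitivity`, `specificity`, `n_cohort`, `test_positives`,
#'   `test_negatives`, `detected_in_positives`, `missed_in_negatives`,
#'   `colonoscopies`, `number_needed_to_scope`, `nns_exact`, plus
#'   unrounded `positives_raw`, `detected_raw`, `missed_raw`.
#' @export
#' @examples
#' flow_single_stage(1000, 0.26, test_spec("VOC", 0.94, 0.69))
flow_single_stage <- function(n = 1000, prevalence, test, label = NULL) {
  stopifnot(inherits(test, "test_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_arg("n must be a positive count")
  if (!is_prob(prevalence)) stop_arg("prevalence must lie in [0, 1]")
  if (is.null(label)) label <- test$name
  .flow_stage(n = n, diseased = n * prevalence, test = test, label = label)
}

# Core stage arithmetic on (possibly non-integer) expected counts.
.flow_stage <- function(n, diseased, test, label) {
  healthy <- n - diseased
  pos_raw <- diseased * test$sensitivity + healthy * (1 - test$specificity)
  det_raw <- diseased * test$sensitivity
  mis_raw <- diseased - det_raw
  positives <- round_half_up(pos_raw)
  detected <- round_half_up(det_raw)
  missed <- round_half_up(mis_raw)
  negatives <- round_half_up(n) - positives
  nns_exact <- if (detected > 0) positives / detected else NA_real_
  out <- data.frame(
    strategy = label,
    sensitivity = test$sensitivity, specificity = test$specificity,
    n_cohort = round_half_up(n),
    test_positives = positives, test_negatives = negatives,
    detected_in_positives = detected, missed_in_negatives = missed,
    colonoscopies = positives,
    number_needed_to_scope = if (is.na(nns_exact)) NA_real_
                             else round_half_up(nns_exact),
    nns_exact = nns_exact,
    positives_raw = pos_raw, detected_raw = det_raw, missed_raw = mis_raw,
    stringsAsFactors = FALSE)
  class(out) <- c("cohort_flow", class(out))
  out
}

#' Per-1000-patient accounting of serial (two-stage) testing
#'
#' Stage 1 gives `first` to everyone; all stage-1 positives go straight to
#' colonoscopy. Stage 2 gives `second` only to the stage-1 negatives, whose
#' disease burden is stage 1's (rounded) missed count; stage-2 positives
#' also get colonoscopy. Total colonoscopies are the positives of both
#' stages; total detected is the sum of detected findings; number needed to
#' scope is colonoscopies per finding detected, rounded half away from
#' zero.
#'
#' The stage-2 input counts are the ROUNDED stage-1 cells (whole patients
#' flow between stages); the unrounded expectations are kept in the `*_raw`
#' columns of each stage row for analysis.
#'
#' @inheritParams flow_single_stage
#' @param first,second [test_spec()] objects for stages 1 and 2.
#' @return List of class `"serial_flow"`: `stages` (two `"cohort_flow"`
#'   rows), and `summary` (one-row data frame with `colonoscopies`,
#'   `detected`, `missed`, `number_needed_to_scope`, `nns_exact`).
#' @export
#' @examples
#' flow_serial(1000, 0.26, test_spec("VOC", 0.94, 0.69),
#'             test_spec("FIT10", 0.54, 0.79))
flow_serial <- function(n = 1000, prevalence, first, second) {
  stage1 <- flow_single_stage(n, prevalence, first)
  if (stage1$test_negatives == 0) {
    warning("no stage-1 negatives: second stage skipped", call. = FALSE)
    stages <- stage1
    colonoscopies <- stage1$colonoscopies
    detected <- stage1$detected_in_positives
    missed <- stage1$missed_in_negatives
  } else {
    stage2 <- .flow_stage(n = stage1$test_negatives,
                          diseased = stage1$missed_in_negatives,
                          test = second,
                          label = paste0(second$name, " (stage 2)"))
    stages <- rbind(stage1, stage2)
    colonoscopies <- stage1$colonoscopies + stage2$colonoscopies
    detected <- stage1$detected_in_positives + stage2$detected_in_positives
    missed <- stage2$missed_in_negatives
  }
  nns_exact <- if (detected > 0) colonoscopies / detected else NA_real_
  summary <- data.frame(
    strategy = paste(first$name, "then", second$name),
    colonoscopies = colonoscopies, detected = detected, missed = missed,
    number_needed_to_scope = if (is.na(nns_exact)) NA_real_
                             else round_half_up(nns_exact),
    nns_exact = nns_exact, stringsAsFactors = FALSE)
  structure(list(stages = stages, summary = summary), class = "serial_flow")
}

#' Colonoscopy-for-all reference strategy
#'
#' Current surveillance practice: every patient is scoped, every high-risk
#' finding is detected (colonoscopy as gold standard), and the number
#' needed to scope is simply 1/prevalence rounded to a whole number.
#'
#' @inheritParams flow_single_stage
#' @return One-row data frame matching the [flow_single_stage()] columns
#'   (test columns `NA`).
#' @export
#' @examples
#' flow_colonoscopy_all(1000, 0.26)
flow_colonoscopy_all <- function(n = 1000, prevalence) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_arg("n must be a positive count")
  if (!is_prob(prevalence)) stop_arg("prevalence must lie in [0, 1]")
  if (prevalence == 0)
    stop_arg("number needed to scope is undefined at zero prevalence")
  detected <- round_half_up(n * prevalence)
  nns_exact <- n / detected
  out <- data.frame(
    strategy = "colonoscopy for all",
    sensitivity = NA_real_, specificity = NA_real_,
    n_cohort = round_half_up(n),
    test_positives = NA_real_, test_negatives = NA_real_,
    detected_in_positives = detected, missed_in_negatives = 0,
    colonoscopies = round_half_up(n),
    number_needed_to_scope = round_half_up(nns_exact),
    nns_exact = nns_exact,
    positives_raw = NA_real_, detected_raw = n * prevalence,
    missed_raw = 0, stringsAsFactors = FALSE)
  class(out) <- c("cohort_flow", class(out))
  out
}

#' Strategy-comparison table for a surveillance cohort
#'
#' Convenience wrapper assembling the three strategies side by side for a
#' cohort of `n` patients: colonoscopy for all, parallel testing (both
#' tests given together; combined performance per `parallel`), and serial
#' testing (`first` then `second` on first-test negatives, two stage rows
#' plus a summary row).
#'
#' @inheritParams flow_serial
#' @param parallel a [test_spec()] for the combined parallel test (e.g.
#'   from [parallel_combine()]).
#' @return Data frame with one row per strategy/stage; serial summary cells
#'   appear in the `colonoscopies`, `number_needed_to_scope` columns of its
#'   stage rows' summary row.
#' @export
flow_table <- function(n = 1000, prevalence, first, second, parallel) {
  all_row <- flow_colonoscopy_all(n, prevalence)
  par_row <- flow_single_stage(n, prevalence, parallel,
                               label = "parallel testing")
  ser <- flow_serial(n, prevalence, first, second)
  ser_rows <- ser$stages
  ser_rows$strategy <- paste("serial:", ser_rows$strategy)
  summary_row <- all_row[0, ]
  summary_row[1, "strategy"] <- "serial: total"
  summary_row$n_cohort <- round_half_up(n)
  summary_row$detected_in_positives <- ser$summary$detected
  summary_row$missed_in_negatives <- ser$summary$missed
  summary_row$colonoscopies <- ser$summary$colonoscopies
  summary_row$number_needed_to_scope <- ser$summary$number_needed_to_scope
  summary_row$nns_exact <- ser$summary$nns_exact
  out <- rbind(all_row, par_row, ser_rows, summary_row)
  rownames(out) <- NULL
  out
}
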