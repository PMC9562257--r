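# Deterministic 255-subject cohort whose FIT values are placed in the
# inter-threshold bins implied by the published confusion counts, so that
# every printed (TP, TN) pair is recovered exactly at the printed cut-offs.
# VOC scores are filler (valid but uninformative).
table2_cutoffs <- c(3, 5, 7, 10, 20, 80, 100, 120)
table2_tp <- c(42, 38, 37, 37, 33, 17, 16, 14)
table2_tn <- c(123, 136, 140, 148, 159, 170, 172, 172)

make_table2_cohort <- function() {
  # representative value for each bin [prev cutoff, cutoff)
  reps <- c(1, 4, 6, 8.5, 15, 50, 90, 110, 150)
  # per-bin counts from successive differences of the exceedance counts
  dis_exceed <- c(68, table2_tp, 0)      # >= 0, >= each cutoff, > max
  hea_exceed <- c(187, 187 - table2_tn, 0)
  dis_bins <- -diff(dis_exceed)
  hea_bins <- -diff(hea_exceed)
  fit <- c(rep(reps, dis_bins), rep(reps, hea_bins))
  status <- c(rep(1L, 68), rep(0L, 187))
  data.frame(subject_id = sprintf("S%03d", seq_len(255)),
             diseased = status, fit_value = fit,
             voc_score = 0.5, stringsAsFactors = FALSE)
}

# small random cohort for brute-force oracles
make_random_cohort <- function(n, seed) {
  with_test_seed(seed, data.frame(
    subject_id = sprintf("R%04d", seq_len(n)),
    diseased = rbinom(n, 1, 0.4),
    fit_value = rlnorm(n, 1, 2),
    voc_score = runif(n),
    stringsAsFactors = FALSE))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

voc_table3 <- data.frame(
  threshold = c(0.78, 0.81, 0.88, 0.94, 0.95),
  tpr = c(0.99, 0.98, 0.94, 0.66, 0.43),
  fpr = 1 - c(0.48, 0.54, 0.69, 0.76, 0.77))
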