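#' Specification of a synthetic surveillance cohort generator
#'
#' Bundles the sample size, seed and class-conditional marker models from
#' which [generate_cohort()] draws. By default the four marker models are
#' calibrated to the published operating points (see
#' [calibration_targets()]): FIT concentrations are log-normal within each
#' class, VOC scores are Beta within each class.
#'
#' @param n_subjects number of subjects to generate (default 255, the
#'   analysed study cohort size).
#' @param seed integer seed; the cohort is a pure function of
#'   (spec, prevalence).
#' @param fit_diseased,fit_healthy `"fit_model"` objects (log-normal), as
#'   returned by [calibrate_fit_model()].
#' @param voc_diseased,voc_healthy `"voc_model"` objects (Beta), as
#'   returned by [calibrate_voc_model()].
#' @param rho Gaussian-copula correlation between FIT and VOC within each
#'   class, in (-1, 1). Default 0: conditional independence given disease
#'   status, which is also what the serial-testing arithmetic assumes; a
#'   nonzero value is exposed for sensitivity analysis only.
#' @param fixed_counts if `TRUE`, the number of diseased subjects is fixed
#'   at `round(n * prevalence)` (half away from zero) rather than drawn
#'   Bernoulli per subject — useful for reproducing printed tables whose
#'   class sizes are exact.
#' @return A list of class `"generator_spec"`.
#' @export
#' @examples
#' spec <- generator_spec(n_subjects = 255, seed = 1)
#' cohort <- generate_cohort(spec, prevalence = 0.26)
generator_spec <- function(n_subjects = 255,
                           seed = 1,
                           fit_diseased = NULL, fit_healthy = NULL,
                           voc_diseased = NULL, voc_healthy = NULL,
                           rho = 0,
                           fixed_counts = FALSE) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop_arg("n_subjects must be a positive count")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_arg("seed must be a single finite number")
  if (!is_prob(rho, lo = -1, hi = 1) || abs(rho) >= 1)
    stop_arg("rho must lie in (-1, 1)")
  tg <- calibration_targets()
  if (is.null(fit_diseased))
    fit_diseased <- calibrate_fit_model(tg$fit_diseased$threshold,
                                        tg$fit_diseased$exceedance)
  if (is.null(fit_healthy))
    fit_healthy <- calibrate_fit_model(tg$fit_healthy$threshold,
                                       tg$fit_healthy$exceedance)
  if (is.null(voc_diseased))
    voc_diseased <- calibrate_voc_model(tg$voc_diseased$threshold,
                                        tg$voc_diseased$exceedance)
  if (is.null(voc_healthy))
    voc_healthy <- calibrate_voc_model(tg$voc_healthy$threshold,
                                       tg$voc_healthy$exceedance)
  stopifnot(inherits(fit_diseased, "fit_model"),
            inherits(fit_healthy, "fit_model"),
            inherits(voc_diseased, "voc_model"),
            inherits(voc_healthy, "voc_model"))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 fit_diseased = fit_diseased, fit_healthy = fit_healthy,
                 voc_diseased = voc_diseased, voc_healthy = voc_healthy,
                 rho = rho, fixed_counts = isTRUE(fixed_counts)),
            class = "generator_spec")
}

#' Generate a synthetic polyp-surveillance cohort
#'
#' Draws one subject record per patient: a binary high-risk-finding status
#' (at least two premalignant polyps including one advanced, or at least
#' five premalignant polyps), a FIT concentration (ug Hb/g faeces) and a
#' VOC classifier score in \[0, 1\], with markers drawn from the
#' class-conditional calibrated models. With `rho != 0` in the spec the two
#' markers share a Gaussian copula within each class.
#'
#' The generator is a pure function of `(spec, prevalence)`: the caller's
#' RNG state is saved and restored, and identical inputs give a
#' bit-identical cohort.
#'
#' @param spec a [generator_spec()].
#' @param prevalence probability of a high-risk finding (default 0.26).
#' @return A data frame with columns `subject_id` (zero-padded, sorted),
#'   `diseased` (integer 0/1), `fit_value` (>= 0) and `voc_score`
#'   (in \[0, 1\]).
#' @export
generate_cohort <- function(spec, prevalence = 0.26) {
  if (!inherits(spec, "generator_spec"))
    stop_arg("spec must be a generator_spec object")
  if (!is_prob(prevalence)) stop_arg("prevalence must lie in [0, 1]")
  n <- spec$n_subjects
  with_seed(spec$seed, {
    if (spec$fixed_counts) {
      n_dis <- as.integer(round_half_up(n * prevalence))
      diseased <- integer(n)
      if (n_dis > 0) diseased[sample.int(n, n_dis)] <- 1L
    } else {
      diseased <- stats::rbinom(n, 1L, prevalence)
    }
    # Gaussian copula: correlated standard normals -> uniforms -> quantiles
    z1 <- stats::rnorm(n)
    z2 <- spec$rho * z1 + sqrt(1 - spec$rho^2) * stats::rnorm(n)
    u_fit <- stats::pnorm(z1)
    u_voc <- stats::pnorm(z2)
    fit_value <- ifelse(
      diseased == 1L,
      stats::qlnorm(u_fit, spec$fit_diseased$meanlog, spec$fit_diseased$sdlog),
      stats::qlnorm(u_fit, spec$fit_healthy$meanlog, spec$fit_healthy$sdlog))
    voc_score <- ifelse(
      diseased == 1L,
      stats::qbeta(u_voc, spec$voc_diseased$shape1, spec$voc_diseased$shape2),
      stats::qbeta(u_voc, spec$voc_healthy$shape1, spec$voc_healthy$shape2))
    data.frame(
      subject_id = sprintf("S%0*d", nchar(as.character(n)), seq_len(n)),
      diseased = diseased,
      fit_value = fit_value,
      voc_score = voc_score,
      stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort as plain CSV
#'
#' The on-disk header is `subject_id,diseased,fit_ug_g,voc_score`, rows
#' ordered by `subject_id`; `read_cohort()` restores the in-memory column
#' names and validates the record invariants (FIT non-negative, score in
#' \[0, 1\], status 0/1).
#'
#' @param cohort a cohort data frame as from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[order(cohort$subject_id),
                c("subject_id", "diseased", "fit_value", "voc_score")]
  names(out) <- c("subject_id", "diseased", "fit_ug_g", "voc_score")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "diseased", "fit_ug_g", "voc_score")
  if (!all(need %in% names(raw)))
    stop_arg("cohort file must have columns ", paste(need, collapse = ", "))
  cohort <- data.frame(subject_id = as.character(raw$subject_id),
                       diseased = as.integer(raw$diseased),
                       fit_value = as.numeric(raw$fit_ug_g),
                       voc_score = as.numeric(raw$voc_score),
                       stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0)
    stop_arg("cohort must be a non-empty data frame")
  need <- c("subject_id", "diseased", "fit_value", "voc_score")
  if (!all(need %in% names(cohort)))
    stop_arg("cohort must have columns ", paste(need, collapse = ", "))
  if (!all(cohort$diseased %in% c(0L, 1L)))
    stop_arg("diseased must be 0/1")
  if (any(!is.finite(cohort$fit_value)) || any(cohort$fit_value < 0))
    stop_arg("fit_value must be finite and non-negative")
  if (any(!is.finite(cohort$voc_score)) ||
      any(cohort$voc_score < 0 | cohort$voc_score > 1))
    stop_arg("voc_score must lie in [0, 1]")
  invisible(cohort)
}
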