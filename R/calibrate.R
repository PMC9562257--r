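#' Published operating points used to calibrate the synthetic cohort
#'
#' The study cohort itself is not deposited, but its marginal marker
#' distributions are pinned down by printed operating points: the FIT
#' confusion counts at several cut-offs (68 high-risk, 187 low-risk
#' subjects) and the VOC sensitivity/specificity pairs at several score
#' thresholds. Two exceedance anchors per class per marker are enough to
#' identify a two-parameter family, and these defaults are the anchors the
#' package calibrates to:
#'
#' * FIT, high-risk class: P(X >= 10) = 37/68, P(X >= 80) = 17/68
#' * FIT, low-risk class: P(X >= 3) = 64/187, P(X >= 10) = 39/187
#' * VOC, high-risk class: P(S >= 0.88) = 0.94, P(S >= 0.94) = 0.66
#' * VOC, low-risk class: P(S >= 0.81) = 0.46, P(S >= 0.88) = 0.31
#'
#' Counts are preferred over rounded rates where both are printed. The
#' cohort prevalence of a high-risk finding is 0.26 (68/255).
#'
#' @return A list with elements `prevalence`, `n_diseased`, `n_healthy`,
#'   and four data frames (`fit_diseased`, `fit_healthy`, `voc_diseased`,
#'   `voc_healthy`), each with columns `threshold` and `exceedance`
#'   (thresholds increasing, exceedances non-increasing).
#' @seealso [calibrate_fit_model()], [calibrate_voc_model()],
#'   [generator_spec()]
#' @export
calibration_targets <- function() {
  list(
    prevalence  = 68 / 255,
    n_diseased  = 68L,
    n_healthy   = 187L,
    fit_diseased = data.frame(threshold = c(10, 80),
                              exceedance = c(37 / 68, 17 / 68)),
    fit_healthy  = data.frame(threshold = c(3, 10),
                              exceedance = c(64 / 187, 39 / 187)),
    voc_diseased = data.frame(threshold = c(0.88, 0.94),
                              exceedance = c(0.94, 0.66)),
    voc_healthy  = data.frame(threshold = c(0.81, 0.88),
                              exceedance = c(0.46, 0.31))
  )
}

check_anchors <- function(thresholds, exceedance, lo = 0, hi = Inf) {
  if (length(thresholds) != 2L || length(exceedance) != 2L)
    stop_arg("calibration needs exactly two (threshold, exceedance) anchors")
  if (any(!is.finite(thresholds)) || any(thresholds <= lo) ||
      any(thresholds >= hi) || thresholds[1] == thresholds[2])
    stop_arg("thresholds must be two distinct values in (", lo, ", ", hi, ")")
  if (any(!is.finite(exceedance)) || any(exceedance <= 0) ||
      any(exceedance >= 1))
    stop_arg("exceedance probabilities must lie strictly in (0, 1)")
  ord <- order(thresholds)
  if (diff(exceedance[ord]) > 0)
    stop_arg("infeasible anchors: exceedance must be non-increasing in ",
             "threshold (got P(X >= ", thresholds[ord[1]], ") = ",
             signif(exceedance[ord[1]], 4), " < P(X >= ", thresholds[ord[2]],
             ") = ", signif(exceedance[ord[2]], 4), ")")
  if (exceedance[ord[1]] == exceedance[ord[2]])
    stop_arg("degenerate anchors: the two exceedances must differ")
  list(threshold = thresholds[ord], exceedance = exceedance[ord])
}

#' Calibrate a log-normal FIT model to two exceedance anchors
#'
#' Finds the log-normal location/scale pair (`meanlog`, `sdlog`) whose
#' survival function passes through two (threshold, exceedance) anchors for
#' one disease class. Writing p = P(X >= t) as
#' 1 - Phi((log t - meanlog)/sdlog), each anchor gives a linear equation in
#' (meanlog, sdlog) via the normal quantile of the log-threshold, so the
#' solution is closed-form and exact.
#'
#' @param thresholds two distinct positive FIT cut-offs (ug Hb/g faeces).
#' @param exceedance the target P(X >= threshold) for each, in (0, 1),
#'   non-increasing in threshold.
#' @return A list of class `"fit_model"` with `meanlog`, `sdlog`, and the
#'   anchors used.
#' @export
#' @examples
#' m <- calibrate_fit_model(c(10, 80), c(37 / 68, 17 / 68))
#' plnorm(c(10, 80), m$meanlog, m$sdlog, lower.tail = FALSE)
calibrate_fit_model <- function(thresholds, exceedance) {
  a <- check_anchors(thresholds, exceedance, lo = 0)
  z <- stats::qnorm(1 - a$exceedance)   # standardised log-thresholds
  sdlog <- diff(log(a$threshold)) / diff(z)
  meanlog <- log(a$threshold[1]) - sdlog * z[1]
  resid <- stats::plnorm(a$threshold, meanlog, sdlog, lower.tail = FALSE) -
    a$exceedance
  if (max(abs(resid)) >= 1e-8)
    stop_arg("log-normal calibration failed to reproduce its anchors ",
             "(max residual ", signif(max(abs(resid)), 3), ")")
  structure(list(meanlog = meanlog, sdlog = sdlog,
                 anchors = data.frame(threshold = a$threshold,
                                      exceedance = a$exceedance)),
            class = "fit_model")
}

#' Calibrate a Beta VOC-score model to two exceedance anchors
#'
#' Finds the Beta shape pair whose survival function passes through two
#' (threshold, exceedance) anchors on (0, 1) for one disease class. The
#' two-equation system has no closed form; it is solved by Nelder-Mead on
#' the log-shapes (which keeps both shapes positive), minimising the sum of
#' squared exceedance residuals, with a small grid of starting points.
#'
#' @param thresholds two distinct score thresholds in (0, 1).
#' @param exceedance the target P(S >= threshold) for each, in (0, 1),
#'   non-increasing in threshold.
#' @param tol maximum absolute residual allowed on either exceedance
#'   equation (default 1e-6); failure to reach it is a calibration error.
#' @return A list of class `"voc_model"` with `shape1`, `shape2`, the
#'   achieved `residual`, and the anchors used.
#' @export
#' @examples
#' m <- calibrate_voc_model(c(0.88, 0.94), c(0.94, 0.66))
#' pbeta(c(0.88, 0.94), m$shape1, m$shape2, lower.tail = FALSE)
calibrate_voc_model <- function(thresholds, exceedance, tol = 1e-6) {
  a <- check_anchors(thresholds, exceedance, lo = 0, hi = 1)
  sse <- function(logshape) {
    p <- stats::pbeta(a$threshold, exp(logshape[1]), exp(logshape[2]),
                      lower.tail = FALSE)
    sum((p - a$exceedance)^2)
  }
  starts <- expand.grid(l1 = c(-1, 0, 1, 2, 3), l2 = c(-1, 0, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(as.numeric(starts[i, ]), sse,
                        control = list(reltol = 1e-15, maxit = 20000))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (best$value < (tol / 10)^2) break
  }
  shape1 <- exp(best$par[1]); shape2 <- exp(best$par[2])
  resid <- max(abs(stats::pbeta(a$threshold, shape1, shape2,
                                lower.tail = FALSE) - a$exceedance))
  if (resid >= tol)
    stop_arg("Beta calibration did not converge for anchors P(S >= ",
             a$threshold[1], ") = ", signif(a$exceedance[1], 4),
             ", P(S >= ", a$threshold[2], ") = ",
             signif(a$exceedance[2], 4),
             " (max residual ", signif(resid, 3), ")")
  structure(list(shape1 = shape1, shape2 = shape2, residual = resid,
                 anchors = data.frame(threshold = a$threshold,
                                      exceedance = a$exceedance)),
            class = "voc_model")
}
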