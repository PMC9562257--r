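#' Round half away from zero
#'
#' Commercial rounding: halves round away from zero, so `round_half_up(0.5)`
#' is 1 and `round_half_up(-0.5)` is -1, unlike [base::round()]'s
#' round-half-to-even. This is the convention used throughout for display
#' figures and per-1000 cohort cells.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep (default 0).
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.345), c(0, 0, 2))
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# a scalar probability in [lo, hi]?
is_prob <- function(x, lo = 0, hi = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= lo && x <= hi
}

stop_arg <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generation is side-effect free.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
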