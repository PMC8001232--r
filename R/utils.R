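# Internal helpers shared across modules.

#' @importFrom rlang abort %||%
NULL

abort_schema <- function(msg, variable = NULL) {
  if (!is.null(variable)) msg <- paste0(msg, " [variable: ", variable, "]")
  abort(msg, class = "crcrisk_schema_error")
}

abort_format <- function(msg) {
  abort(msg, class = "crcrisk_format_error")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Truncated normal on [lo, hi] via inverse-CDF; vectorised over n.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, p_lo, p_hi)
  pmin(pmax(stats::qnorm(u, mean, sd), lo), hi)
}

# Truncated exponential on [0, 1] with decay rate `rate`; rate = Inf collapses
# to a point mass at 0. Mass decays away from 0.
rtruncexp01 <- function(n, rate) {
  if (is.infinite(rate)) return(rep(0, n))
  if (rate <= 0) return(stats::runif(n))
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate))) / rate
}

# Truncate (not round) x to `digits` decimals, as some printed figures are.
truncate_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

# Number of decimals a printed figure carries (71.1 -> 1, 72.72 -> 2, 4 -> 0).
printed_decimals <- function(x, max_digits = 4L) {
  for (d in 0:max_digits) {
    if (isTRUE(all.equal(round(x, d), x, tolerance = 1e-9))) return(d)
  }
  max_digits
}

# Does exact value x reproduce the printed figure under rounding or truncation?
matches_printed <- function(x, printed, digits = printed_decimals(printed)) {
  by_round <- abs(round(x, digits) - printed) < 1e-9
  by_trunc <- abs(truncate_decimals(x, digits) - printed) < 1e-9
  c(round = by_round, trunc = by_trunc)
}
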