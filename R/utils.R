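# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimals, as used in
#' clinical report tables. Base `round()` rounds half to even, which turns
#' 10.75 into 10.7 rather than the 10.8 a report table prints.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Count and percentage
#'
#' @param count Number of events.
#' @param total Denominator.
#' @param digits Decimals for the percentage (default 1).
#' @return Percentage on the 0-100 scale, rounded half up.
#' @export
proportion_pct <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0, count <= total)
  round_half_up(100 * count / total, digits)
}

# stop() with a consistent error class so callers can distinguish
# configuration errors from data errors
abort_config <- function(msg) {
  stop(errorCondition(msg, class = c("leaktraj_config_error", "error")))
}

abort_data <- function(msg) {
  stop(errorCondition(msg, class = c("leaktraj_data_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
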