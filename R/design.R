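# Deterministic study-design arithmetic: finite-population sample size and
# descriptive summaries.

#' Finite-population minimum sample size
#'
#' Cochran's sample size with finite-population correction:
#' `n = ceil( N * q / ((N - 1) * e^2 + q) )` with `q = z^2 * p * (1 - p)`,
#' `z` the two-sided normal quantile of the confidence level, `e` the
#' margin of error and `p` the anticipated response fraction. For a yearly
#' surgical volume of 420, a 5% margin and 95% confidence this gives the
#' minimum of 201 patients.
#'
#' @param population_size Finite population size `N` (>= 1).
#' @param margin Margin of error `e` as a fraction in (0, 1); default 0.05.
#' @param confidence Confidence level; default 0.95.
#' @param p Anticipated proportion; default 0.5 (most conservative).
#' @return Minimum sample size (integer).
#' @export
finite_population_sample_size <- function(population_size, margin = 0.05,
                                          confidence = 0.95, p = 0.5) {
  if (population_size < 1) abort_config("population_size must be >= 1")
  if (margin <= 0 || margin >= 1) abort_config("margin must be in (0, 1)")
  if (p <= 0 || p >= 1) abort_config("p must be in (0, 1)")
  if (confidence <= 0 || confidence >= 1) {
    abort_config("confidence must be in (0, 1)")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  q <- z^2 * p * (1 - p)
  n <- population_size * q / ((population_size - 1) * margin^2 + q)
  as.integer(ceiling(n))
}

#' Descriptive summary of categorical patient attributes
#'
#' Frequencies and percentages (half-up, 1 decimal) per category, the way
#' clinical baseline tables report them.
#'
#' @param x Vector of category labels.
#' @param digits Decimals for percentages.
#' @return A tibble with `level`, `count`, `pct`.
#' @export
describe_categorical <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort_data("no observations to describe")
  tab <- table(x)
  tibble::tibble(
    level = names(tab),
    count = as.integer(tab),
    pct = proportion_pct(as.integer(tab), length(x), digits)
  )
}

#' Descriptive summary of a continuous attribute
#'
#' @param x Numeric vector.
#' @return A tibble with `mean`, `sd`, `min`, `max`, `n`.
#' @export
describe_continuous <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) abort_data("no observations to describe")
  tibble::tibble(
    mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
    n = length(x)
  )
}
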