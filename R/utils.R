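#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; descriptive tables here use
#' the half-up convention so printed percentages match hand arithmetic.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # small epsilon guards against binary representations just below .5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage under the reporting convention used throughout the package
#'
#' `100 * count / denom`, rounded half-up to two decimals.
#'
#' @param count numerator count(s).
#' @param denom denominator count(s).
#' @return numeric percentage(s).
#' @export
report_pct <- function(count, denom) {
  round_half_up(100 * count / denom, 2)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
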