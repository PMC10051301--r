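#' Round half away from zero
#'
#' Rounds to the nearest value at the given number of decimal digits, with
#' exact halves rounded up (away from zero for positive input). All
#' percentages reported by the pipeline use this rule, so that 41/55 -> 75,
#' 3/8 -> 38 and 4/9 -> 44 when expressed as whole percentages.
#'
#' @param x numeric vector.
#' @param digits integer, decimal digits to keep (default 0).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(37.5)   # 38
#' round_half_up(74.54)  # 75
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Whole-number percentage of a fraction
#'
#' @param num numerator (count).
#' @param den denominator (count), must be positive.
#' @return integer percentage, rounded half-up.
#' @export
percent_half_up <- function(num, den) {
  stopifnot(den > 0)
  round_half_up(100 * num / den)
}

## unscaled median absolute deviation (no 1.4826 consistency factor)
mad_raw <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

## even-length median = mean of the two central order statistics
## (stats::median already does this; alias kept for readability)
median_mid <- stats::median
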