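#' Round half away from zero
#'
#' Integer rounding where .5 always moves away from zero (the convention used
#' for reported occurrence percentages), unlike base R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_away(c(57.89, 0.5, -0.5, 26.3))
#' @export
round_half_away <- function(x) {
  trunc(x + 0.5 * sign(x))
}

# Draw n values log-uniformly over [lo, hi], lo > 0.
runif_log <- function(n, lo, hi) {
  stopifnot(lo > 0, hi >= lo)
  exp(runif(n, log(lo), log(hi)))
}

# Split a semicolon-delimited field into a character vector ("" -> empty).
split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_field <- function(x) paste(x, collapse = ";")
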