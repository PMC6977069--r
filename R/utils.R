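#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in ecological
#' tables conventionally round half away from zero (so 18.55 -> 18.6,
#' 2.5 -> 3). Used by every percentage-formatting path in the package.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a fraction as a printed percentage share
#'
#' Default convention: shares of at least 10% are printed as integers,
#' smaller shares with one decimal. `digits` overrides the convention.
#'
#' @param frac fraction in \[0,1\] (or any numeric; multiplied by 100).
#' @param digits optional integer forcing a fixed number of decimals.
#' @return numeric percentage on the 0-100 scale, rounded half away from zero.
#' @export
format_share <- function(frac, digits = NULL) {
  pct <- 100 * frac
  if (is.null(digits)) {
    digits <- ifelse(abs(pct) >= 10, 0L, 1L)
  }
  round_half_away(pct, digits)
}

# internal: stop() with call. = FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)

# internal: canonical unordered-pair key
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

# internal: NULL-coalescing
`%||%` <- function(a, b) if (is.null(a)) b else a
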