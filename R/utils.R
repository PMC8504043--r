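#' Round half away from zero
#'
#' Table-style rounding (0.05 -> 0.1), unlike \code{round()}'s
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# percent with one decimal, half away from zero, as the tables print it
format_percent <- function(p) sprintf("%.1f", round_half_up(p, 1))

`%||%` <- function(a, b) if (is.null(a)) b else a
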