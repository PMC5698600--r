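#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (so 0.0005 -> 0.001 at three
#' decimals), the convention used for all displayed statistics in this
#' package. Base [round()] rounds half to even, which would disagree with the
#' printed tables this package reproduces.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 3).
#' @return Numeric vector, rounded.
#' @examples
#' round_half_up(c(0.0005, -0.0005, 2.6135), 3)
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a numeric vector for TSV output: fixed decimals, NA as an em-dash.
format_cell <- function(x, digits = 3) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  out[is.na(x)] <- "—"
  out
}

# Stop with a classed error (condition classes make failures testable).
stop_enorthern <- function(msg, class) {
  abort(msg, class = c(class, "enorthern_error"))
}
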