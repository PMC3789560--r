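#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character strings restricted to
#' the alphabet `A`, `C`, `G`, `T`, `N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "AAG"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Round half away from zero
#'
#' Decimal rounding in which exact ties go up (`0.125 -> 0.13` at two
#' digits), the convention used for all reported percentages and marker
#' intervals. Base [round()] uses round-half-to-even instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a parent count
#'
#' `100 * n / total`, rounded half-up to two decimals — the form in which
#' stage shares of the marker-refinement funnel are reported.
#'
#' @param n Numerator count(s).
#' @param total Denominator count(s).
#' @return Numeric percentage(s) rounded to 2 decimals.
#' @examples
#' pct_of(9240, 25437) # 36.33
#' @export
pct_of <- function(n, total) {
  stopifnot(all(total > 0))
  round_half_up(100 * n / total, 2)
}

# split a string into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# number of equal characters between two equal-length strings (byte-wise)
n_matching_chars <- function(a, b) {
  sum(charToRaw(a) == charToRaw(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
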