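# Small shared helpers. Kept base-R and dependency-free.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding in which ties go away from zero (so 0.05 -> 0.1 at one
#' decimal), matching how clinical tables conventionally render percentages.
#' Base `round()` uses banker's rounding and would print 0.25 as 0.2.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @export
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, table-rendered
#'
#' Computes `100 * count / denom` rounded half-away-from-zero to one
#' decimal — the form in which prevalence cells are printed.
#'
#' @param count Numerator count(s).
#' @param denom Denominator count(s).
#' @return Numeric percentage(s) with one decimal.
#' @export
pct_of <- function(count, denom) {
  stopifnot(all(denom > 0))
  round_half_out(100 * count / denom, 1)
}

#' Render a "count (pct%)" table cell
#'
#' @param count Integer count(s).
#' @param denom Denominator count(s).
#' @return Character vector like `"4,553 (7.7%)"`.
#' @export
render_count_pct <- function(count, denom) {
  sprintf("%s (%s%%)",
          formatC(count, format = "d", big.mark = ","),
          formatC(pct_of(count, denom), format = "f", digits = 1))
}

# stop() with sprintf formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Truncated-normal draws by inverse-CDF (support [lo, hi]).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Deterministic config hash: md5 of the canonical JSON serialisation.
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}
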