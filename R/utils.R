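#' Round half away from zero
#'
#' Decimal rounding where exact halves round up in magnitude (`0.125 -> 0.13`
#' at 2 digits), matching how pharmacovigilance tables are conventionally
#' printed. Base [round()] uses banker's rounding and would print `0.12`.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a total, printed-table style
#'
#' @param count Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places (half-up rounding).
#' @return Numeric percentage on the 0-100 scale.
#' @export
#' @examples
#' pct_of(3470, 84462, 1) # 4.1
pct_of <- function(count, total, digits = 2) {
  if (total <= 0) return(NA_real_)
  round_half_up(100 * count / total, digits)
}

# Internal: stop with a classed condition so callers can test error classes.
abort_dilinet <- function(message, class) {
  rlang::abort(message, class = c(class, "dilinet_error"))
}

# Internal: check a scalar probability-like field, naming the field on failure.
check_prob <- function(x, field, lower = 0, upper = 1,
                       lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    abort_dilinet(
      sprintf("invalid value for '%s': must be a number in %s%g, %g%s",
              field,
              if (lower_open) "(" else "[", lower, upper,
              if (upper_open) ")" else "]"),
      "dilinet_validation_error"
    )
  }
  invisible(x)
}
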