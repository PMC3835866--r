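#' Round half away from zero
#'
#' Registry reports conventionally round percentages half-up (so 5.25 -> 5.3),
#' unlike [base::round()]'s round-half-to-even. Used for all printed
#' percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded to one decimal
#'
#' @param n numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 1, the reporting convention).
#' @return percentage(s); `NA_real_` when `total` is zero (undefined, never 0).
#' @export
pct_of <- function(n, total, digits = 1) {
  if (length(total) != 1L || is.na(total) || total == 0) {
    return(rep(NA_real_, length(n)))
  }
  round_half_up(100 * n / total, digits)
}

# internal: stop with a classed condition so callers can test error types
stop_sgapaf <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sgapaf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

warn_sgapaf <- function(msg, class, ...) {
  warning(structure(
    class = c(class, "sgapaf_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# internal: %||%
`%||%` <- function(a, b) if (is.null(a)) b else a
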