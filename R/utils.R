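# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Presentation rounding used throughout the report surface: halves round
#' up in magnitude (0.4345 -> 0.435 at 3 digits), unlike [base::round()]'s
#' round-half-to-even. Internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.0005, 0.4345, -0.0005), 3)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an epsilon scaled to x to defeat binary representation of .5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "clinstage_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# scalar checks
is_count1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
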