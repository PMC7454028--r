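#' Round half away from zero
#'
#' Deterministic commercial rounding used everywhere a count or a displayed
#' percentage is derived from a product of a rate and a count. Base
#' [base::round()] rounds half to even, which would make integer recruit and
#' emigrant counts depend on the parity of the neighbouring integer; field
#' tables round half up, and the simulator follows the same convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))      # 1 2 3
#' roundHalfUp(14.815, 2)             # 14.82 (but 14.8148 -> 14.81)
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Stop with the calling function's name, Bioconductor style.
.stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

.warnf <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

## scalar integer coercion with domain check
.asCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x))
    .stopf("'%s' must be a single non-negative integer", name)
  x <- as.integer(x)
  if (x < min) .stopf("'%s' must be >= %d", name, min)
  x
}

.checkProb <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    .stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}
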