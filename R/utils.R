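#' Truncate (not round) to a fixed number of decimal places
#'
#' Display convention used throughout the cohort summaries: values are cut,
#' never rounded, so 2/1544 as a percentage prints as 0.12 and 1/845 prints
#' as 0.0011. A guard of 1e-9 is added before truncation to absorb binary
#' floating-point representation error (so 1/250 * 1e4 truncates to 40, not
#' 39); values genuinely within 1e-9 below a decimal boundary are therefore
#' carried up, which is far below the displayed precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` truncated to `digits` decimals.
#' @export
trunc_decimal <- function(x, digits) {
  stopifnot(is.numeric(x), digits >= 0)
  f <- 10^digits
  trunc(x * f + 1e-9) / f
}

# internal: stop() with a consistent prefix-free message built by sprintf
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
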