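#' Round half away from zero
#'
#' Commercial rounding as used for reported heritabilities: ties go away from
#' zero, so `round_half_up(0.125, 2)` is `0.13` (base [round()] would give
#' `0.12` under banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.415, 2) # 0.42
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## Validate a scalar in a (possibly open) range; used by parameter checks.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s",
                 name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

## Derive a child seed from a base seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
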