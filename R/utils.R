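#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used only when formatting monetary
#' amounts for reporting; all internal computation keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  trunc(x * f + sign(x) * 0.5) / f
}

# Deterministically derive a 32-bit stage seed from a top-level seed and a
# label, so that independent pipeline stages get reproducible, distinct
# streams. Stage seeds depend only on (seed, label), never on call order.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop()/warning() wrappers that keep the call out of the message
tc_stop <- function(...) stop(..., call. = FALSE)
tc_warn <- function(...) warning(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
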