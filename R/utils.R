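#' Round half away from zero
#'
#' Reported costs and p-values use conventional "round half up" formatting
#' (0.0335 -> 0.034), not the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)        # 3, not 2
#' round_half_up(0.0485, 3)  # 0.049
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() with a condition class so callers/tests can target stonecea errors
abort_stonecea <- function(msg, class = "stonecea_error", ...) {
  rlang::abort(msg, class = c(class, "stonecea_error"), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
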