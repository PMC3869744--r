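# internal helpers shared across the package

#' Round to the nearest integer, halves away from zero
#'
#' Deterministic alternative to banker's rounding so that scores ending in
#' .5 always move away from zero, giving bit-reproducible rounded scores.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# stop() with a consistent condition class so tests can assert on it
abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("cgs_validation_error", "error")))
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort_validation(msg)
  invisible(TRUE)
}

is_proportion <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0) && all(x < 1)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
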