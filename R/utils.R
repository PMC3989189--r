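#' Round half away from zero
#'
#' Integer rounding used for all reported percentages, so that recomputed
#' percentages match conventional manuscript rounding (e.g. 91.55 -> 92)
#' rather than R's round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Percentage with half-away-from-zero rounding
#'
#' @param count numerator.
#' @param denominator denominator, must be positive.
#' @return integer percentage.
#' @export
percent_of <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * count / denominator)
}

# Derive a child seed from a base seed; keeps results within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
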