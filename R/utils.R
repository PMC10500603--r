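# Internal helpers shared across modules.

# Half-up rounding, e.g. for converting printed prevalences back to counts
# (base round() is banker's rounding, which breaks 0.5 cases).
round_half_up <- function(x) floor(x + 0.5)

#' Convert a printed percentage to an affected count
#'
#' Reconstructs an integer count from a prevalence printed as a whole
#' percentage, using half-up rounding: `floor(percent/100 * n + 0.5)`.
#' Useful for rebuilding contingency tables from published demographic
#' tables that report only percentages.
#'
#' @param percent Percentage in `[0, 100]`.
#' @param n Group size the percentage refers to.
#' @return Integer count(s).
#' @examples
#' count_from_percent(22, 111)  # 24
#' count_from_percent(7, 111)   # 8
#' @export
count_from_percent <- function(percent, n) {
  stopifnot(is.numeric(percent), is.numeric(n), all(n > 0))
  if (any(percent < 0 | percent > 100)) {
    abort("`percent` must lie in [0, 100].")
  }
  as.integer(round_half_up(percent / 100 * n))
}

# Deterministically spawn `n` child seeds from one master seed, so that
# individual simulation replicates can be replayed in isolation.
child_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 0)
  if (n == 0) return(integer(0))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Scalar finite-number check used in argument validation.
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

assert_seed <- function(seed) {
  if (!is_number(seed)) abort("`seed` must be a single finite number.")
  as.integer(seed)
}
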