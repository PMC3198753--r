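# Internal helpers shared across the pipeline.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with exact halves going up, the convention used
#' when printing percentage tables (base R's `round()` rounds half to even).
#' A tiny epsilon absorbs binary representation error so values like
#' 4.4938 -> 4.5 and 27.995 -> 28.0 print as intended.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.05, 0.15, 2.0756), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# One-decimal percentage with an undefined marker (NA) for zero denominators.
# Rounds half-up through an intermediate two-decimal step: published
# percentage tables of this kind are double-rounded (software reports two
# decimals, tables print one), and only this convention reproduces every
# printed cell (e.g. 9.948 -> 9.95 -> 10.0, where direct rounding gives 9.9).
pct1 <- function(num, den) {
  den <- rep_len(den, length(num))
  out <- rep(NA_real_, length(num))
  ok <- den > 0
  out[ok] <- round_half_up(round_half_up(100 * num[ok] / den[ok], 2), 1)
  out
}

# deterministic substream seed: every stochastic operation draws from its own
# substream derived from the user's single seed plus a stage label
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) %% 65536 * 30269 + h * 7919 + 1) %% 2147483629)
}

# sample() without the length-1 surprise (sample(5L, ...) samples 1:5)
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

stop_invalid <- function(msg) {
  abort(msg, class = "lsaminer_invalid_argument")
}

stop_degenerate <- function(msg) {
  abort(msg, class = "lsaminer_degenerate_input")
}

# character sort/order in C locale so vocabularies are platform-stable
sort_c <- function(x) x[order(x, method = "radix")]
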