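# Meaningful / meaningless classification of whole responses.
# Whole responses matching a catalogued null pattern are removed; words are
# never removed from responses that survive.

#' Normalize a response for pattern matching
#'
#' Lower-cases, removes punctuation and digits, collapses runs of
#' whitespace to single spaces, and trims. `"N/A"` becomes `"na"`,
#' `"  No.  "` becomes `"no"`.
#'
#' @param text Character vector.
#' @return Character vector of normalized strings.
#' @export
normalize_pattern <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("[^a-z[:space:]]+", "", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Classify responses as meaningful or meaningless
#'
#' A response is meaningless iff its normalized text is empty or is an
#' exact member of the null-pattern set. Exact whole-response matching
#' (never substring or regex) deliberately errs toward calling a response
#' meaningful: an uncatalogued null string slips through as meaningful,
#' but informative text is never discarded.
#'
#' @param text Character vector of response texts (or a response tibble
#'   with a `text` column).
#' @param patterns Null patterns from [read_null_patterns()] (nonempty).
#' @return Logical vector: TRUE = meaningful.
#' @export
#' @examples
#' pats <- read_null_patterns()
#' classify_meaningful(c("I have nothing to say", "Exposure to welding fumes."), pats)
classify_meaningful <- function(text, patterns) {
  if (is.data.frame(text)) text <- text$text
  if (length(patterns) == 0) stop_invalid("`patterns` must be nonempty")
  norm <- normalize_pattern(text)
  nzchar(norm) & !(norm %in% patterns)
}

#' Partition responses into meaningful and meaningless sets
#'
#' Applies [classify_meaningful()] and optionally a human-review override
#' file (the audit workflow: a reviewer can force individual responses to
#' either label after automatic classification). Participants whose only
#' response is meaningless are treated as non-responders in all downstream
#' propensity analyses.
#'
#' @param responses Tibble with `response_id` and `text` columns.
#' @param patterns Null patterns from [read_null_patterns()].
#' @param overrides Optional tibble (`response_id`, `meaningful` logical)
#'   of forced labels, applied after automatic classification.
#' @return List with tibbles `meaningful` and `meaningless` (a partition of
#'   the input) and a one-row `counts` tibble.
#' @export
split_responses <- function(responses, patterns, overrides = NULL) {
  flag <- classify_meaningful(responses$text, patterns)
  if (!is.null(overrides)) {
    stopifnot(all(c("response_id", "meaningful") %in% names(overrides)))
    i <- match(overrides$response_id, responses$response_id)
    ok <- !is.na(i)
    flag[i[ok]] <- overrides$meaningful[ok]
  }
  list(
    meaningful = responses[flag, , drop = FALSE],
    meaningless = responses[!flag, , drop = FALSE],
    counts = tibble(
      n_responses = nrow(responses),
      n_meaningful = sum(flag),
      n_meaningless = sum(!flag)
    )
  )
}

#' Draw a seeded audit sample for human review
#'
#' Uniform sample without replacement from a classified response set, for
#' manual verification of the automatic labels (the workflow behind the
#' override file of [split_responses()]).
#'
#' @param responses Tibble of classified responses.
#' @param n Sample size, `n <= nrow(responses)`.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @param path Optional path; when given, the sample is also written as a
#'   TSV review sheet.
#' @return Tibble of `n` sampled rows, in sampled order.
#' @export
audit_sample <- function(responses, n, seed, path = NULL) {
  if (n > nrow(responses)) {
    stop_invalid("`n` exceeds the number of responses")
  }
  out <- withr::with_seed(
    substream_seed(seed, "audit_sample"),
    responses[resample(seq_len(nrow(responses)), n), , drop = FALSE]
  )
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}
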