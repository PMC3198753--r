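# Shipped plain-text fixtures: the clustering stop list and the null-pattern
# bank. Both accept user-supplied replacements via `path`.

#' High-frequency clustering stop list
#'
#' Function words excluded when selecting clustering terms from meaningful
#' responses. The stop list plays no role in semantic-space construction:
#' every word of every response enters the term-document matrix, and only
#' whole meaningless responses are ever removed.
#'
#' @param path Optional path to a user-supplied stop list (UTF-8, one word
#'   per line, `#` comments). Defaults to the fixture shipped with the
#'   package (~150 English function words).
#' @return Character vector of stop words.
#' @export
lsa_stoplist <- function(path = NULL) {
  path <- path %||% system.file("extdata", "clustering_stoplist.txt",
    package = "lsaminer", mustWork = TRUE
  )
  read_word_lines(path)
}

#' Null-pattern bank
#'
#' Loads the set of normalized response strings that mark a whole response as
#' meaningless (e.g. "no", "na", "i have nothing to say"). Patterns are
#' normalized with [normalize_pattern()] and deduplicated on load; matching
#' against responses is exact on the normalized full response, which biases
#' classification toward calling a response meaningful.
#'
#' The shipped bank is a synthetic stand-in of ~65 common null strings; the
#' original study identified far more patterns in its (unavailable) data, so
#' users with real data should extend it via `path`.
#'
#' @param path Optional path to a pattern file (UTF-8, one pattern per line,
#'   `#` comments). Defaults to the shipped fixture.
#' @return Character vector of normalized, deduplicated patterns with a
#'   `provenance` attribute (`"fixture"` or `"user-supplied"`).
#' @seealso [classify_meaningful()], [split_responses()]
#' @export
read_null_patterns <- function(path = NULL) {
  provenance <- if (is.null(path)) "fixture" else "user-supplied"
  path <- path %||% system.file("extdata", "null_patterns.txt",
    package = "lsaminer", mustWork = TRUE
  )
  raw <- read_word_lines(path, collapse_inner = FALSE)
  pats <- unique(normalize_pattern(raw))
  pats <- pats[nzchar(pats)]
  structure(pats, provenance = provenance)
}

read_word_lines <- function(path, collapse_inner = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}
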