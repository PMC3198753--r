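# Tokenization and construction of the weighted term-document matrix.

#' Tokenize free text
#'
#' Lower-cases, collapses hyphens/apostrophes between letters ("don't" ->
#' "dont"), strips all remaining punctuation and digits, and splits on
#' whitespace. Token order is preserved; empty input yields an empty
#' token vector. No stemming and no stop list: surface forms are kept so
#' that context, not preprocessing, disambiguates meaning.
#'
#' @param text Character vector.
#' @return A list of character token vectors, one per input string.
#' @export
#' @examples
#' tokenize("Exposure to welding fumes.")[[1]]
tokenize <- function(text) {
  x <- tolower(as.character(text))
  x <- gsub("(?<=[a-z])['’‘-](?=[a-z])", "", x, perl = TRUE)
  x <- gsub("[^a-z]+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

# accept a document tibble (text column), character vector, or token list
doc_tokens <- function(docs) {
  if (is.data.frame(docs)) {
    if (!"text" %in% names(docs)) stop_invalid("`docs` needs a `text` column")
    tokenize(docs$text)
  } else if (is.list(docs)) {
    docs
  } else {
    tokenize(docs)
  }
}

#' Build a corpus vocabulary
#'
#' Counts term frequencies over the whole corpus with a single pass and
#' assigns contiguous integer indices (1..T, C-locale alphabetical order) to
#' every term whose corpus frequency is at least `min_count`.
#'
#' @param docs Document tibble with a `text` column, a character vector of
#'   documents, or a list of token vectors.
#' @param min_count Minimum corpus frequency for a term to be indexed
#'   (default 1: every term is kept).
#' @return Tibble with columns `term`, `index`, `frequency`.
#' @export
build_vocabulary <- function(docs, min_count = 1) {
  toks <- doc_tokens(docs)
  if (length(toks) == 0) stop_invalid("empty corpus: no documents")
  counts <- table(unlist(toks, use.names = FALSE))
  if (length(counts) == 0) stop_invalid("empty corpus: no tokens")
  keep <- counts[counts >= min_count]
  if (length(keep) == 0) {
    warn("`min_count` exceeds every term frequency; vocabulary is empty")
    return(tibble(term = character(), index = integer(), frequency = integer()))
  }
  terms <- sort_c(names(keep))
  tibble(
    term = terms,
    index = seq_along(terms),
    frequency = as.integer(keep[terms])
  )
}

#' Build the weighted term-document matrix
#'
#' Raw weighting puts the count of term t in document d at entry (t, d).
#' Log-entropy weighting -- the canonical LSA scheme -- replaces each entry
#' with `log(1 + count) * g_t`, where the global weight
#' `g_t = 1 - H_t / log(D)` discounts terms whose occurrences are spread
#' evenly over the corpus (`H_t` is the Shannon entropy of term t's
#' distribution over documents). A term appearing uniformly in every
#' document gets global weight 0; terms concentrated in few documents keep
#' weight near 1. Vocabulary terms absent from `docs` yield zero rows.
#'
#' @param docs Documents (tibble with `text`, character vector, or token
#'   list); the vocabulary must come from these documents or a superset.
#' @param vocab Vocabulary tibble from [build_vocabulary()].
#' @param weighting `"log_entropy"` (default) or `"raw"`.
#' @return Object of class `term_doc_matrix`: a list with the sparse
#'   weighted `matrix` (terms x documents, `dgCMatrix`), the `weighting`
#'   tag, per-term `global_weights` (1 for raw weighting), and the `vocab`.
#' @export
build_term_doc_matrix <- function(docs, vocab,
                                  weighting = c("log_entropy", "raw")) {
  if (!is.character(weighting) ||
    !all(weighting %in% c("log_entropy", "raw"))) {
    stop_invalid("unknown `weighting`; use \"log_entropy\" or \"raw\"")
  }
  weighting <- match.arg(weighting)
  toks <- doc_tokens(docs)
  n_terms <- nrow(vocab)
  n_docs <- length(toks)
  idx <- lapply(toks, function(t) {
    i <- match(t, vocab$term)
    i[!is.na(i)]
  })
  counts <- Matrix::sparseMatrix(
    i = unlist(idx, use.names = FALSE),
    j = rep.int(seq_len(n_docs), lengths(idx)),
    x = 1,
    dims = c(n_terms, n_docs),
    dimnames = list(vocab$term, NULL)
  )

  if (weighting == "raw") {
    g <- rep(1, n_terms)
  } else {
    g <- log_entropy_weights(counts)
  }
  names(g) <- vocab$term

  trip <- methods::as(counts, "TsparseMatrix")
  weighted <- Matrix::sparseMatrix(
    i = trip@i + 1L, j = trip@j + 1L,
    x = if (weighting == "raw") trip@x else log1p(trip@x) * g[trip@i + 1L],
    dims = dim(counts), dimnames = dimnames(counts)
  )

  structure(
    list(
      matrix = weighted, weighting = weighting,
      global_weights = g, vocab = vocab, n_docs = n_docs
    ),
    class = "term_doc_matrix"
  )
}

# g_t = 1 - H_t/log(D); single-document corpora get weight 1 by convention
log_entropy_weights <- function(counts) {
  n_terms <- nrow(counts)
  n_docs <- ncol(counts)
  if (n_docs == 1) {
    return(rep(1, n_terms))
  }
  trip <- methods::as(counts, "TsparseMatrix")
  row_tot <- Matrix::rowSums(counts)
  p <- trip@x / row_tot[trip@i + 1L]
  contrib <- rowsum(p * log(p), trip@i + 1L)
  h <- numeric(n_terms)
  h[as.integer(rownames(contrib))] <- -contrib[, 1]
  pmax(0, 1 - h / log(n_docs))
}

#' @export
print.term_doc_matrix <- function(x, ...) {
  cat(
    "<term_doc_matrix> ", nrow(x$matrix), " terms x ", ncol(x$matrix),
    " documents (", x$weighting, " weighting, ",
    format(Matrix::nnzero(x$matrix)), " nonzero entries)\n",
    sep = ""
  )
  invisible(x)
}

#' Persist a term-document matrix
#'
#' Writes the sparse weighted matrix in MatrixMarket format plus a sidecar
#' TSV vocabulary (`term`, `index`, `frequency`).
#'
#' @param tdm A [build_term_doc_matrix()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_term_doc_matrix <- function(tdm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(tdm$matrix, file.path(dir, "tdm.mtx"))
  readr::write_tsv(tdm$vocab, file.path(dir, "vocabulary.tsv"))
  invisible(dir)
}
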