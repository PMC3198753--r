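# Shared fixtures, all built in code at test time.

# wrap a plain numeric matrix as a raw-weighted term-document matrix
as_tdm <- function(m) {
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("t%03d", seq_len(nrow(m)))
  }
  structure(
    list(
      matrix = Matrix::Matrix(m, sparse = TRUE),
      weighting = "raw",
      global_weights = stats::setNames(rep(1, nrow(m)), rownames(m)),
      vocab = tibble::tibble(
        term = rownames(m),
        index = seq_len(nrow(m)),
        frequency = pmax(1L, as.integer(rowSums(m > 0)))
      ),
      n_docs = ncol(m)
    ),
    class = "term_doc_matrix"
  )
}

# semantic space with fully controlled geometry (orthonormal U assumed)
fake_space <- function(u, d, v = NULL, weighting = "raw") {
  structure(
    list(
      U = u, singular_values = d,
      V = v %||% matrix(0, 1, length(d)), k = length(d),
      weighting = weighting,
      global_weights = stats::setNames(rep(1, nrow(u)), rownames(u)),
      vocab = tibble::tibble(
        term = rownames(u), index = seq_len(nrow(u)),
        frequency = 1L
      )
    ),
    class = "semantic_space"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small planted-topic model over an alphabetic background pool
tiny_tm <- function(n_topics = 3, seed = 1) {
  topic_model(
    n_topics = n_topics,
    background = paste0("filler", letters[1:20]),
    seed = seed
  )
}

# 2x2 cohort: exposed responders/non, unexposed responders/non
records_from_2x2 <- function(a, b, c, d) {
  tibble::tibble(
    responded = rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d)),
    exposure = rep(c("yes", "yes", "no", "no"), times = c(a, b, c, d))
  )
}

# small but complete synthetic run shared by clustering/assignment tests
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_pipeline(
        run_config(
          seed = 42, n_docs = 600, n_participants = 2500,
          n_topics = 4, k = 20, k_c = 4, min_freq = 70
        )
      )
    }
    cache
  }
})
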