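# The rank-k semantic space: truncated SVD of the weighted term-document
# matrix, passage fold-in, and cosine similarity.

#' Build a rank-k semantic space
#'
#' Computes the best rank-k factorization `U_k S_k V_k'` of the weighted
#' term-document matrix (minimum Frobenius reconstruction error among
#' rank-k matrices). Trailing numerically-zero singular values are dropped
#' and `k` reduced accordingly. The sign of each singular-vector pair is
#' fixed so the largest-magnitude entry of the term vector is positive,
#' making results reproducible despite the inherent SVD sign ambiguity.
#'
#' Production LSA spaces conventionally use k = 300; desk-scale synthetic
#' corpora support far smaller k (the planted structure here is recovered
#' well at k around 50).
#'
#' @param tdm A [build_term_doc_matrix()] result.
#' @param k Number of dimensions, `1 <= k <= min(T, D)`.
#' @return Object of class `semantic_space` with term vectors `U`
#'   (terms x k, rownames = terms), nonincreasing positive
#'   `singular_values`, document vectors `V` (documents x k), the achieved
#'   `k`, the weighting tag, per-term global weights (reused by
#'   [fold_in()]), and the vocabulary.
#' @seealso [fold_in()], [term_vectors()], [cosine_sim()]
#' @export
build_space <- function(tdm, k) {
  stopifnot(inherits(tdm, "term_doc_matrix"))
  m <- tdm$matrix
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > min(dim(m))) {
    stop_invalid(sprintf(
      "`k` must be in [1, %d] (min of matrix dimensions)", min(dim(m))
    ))
  }
  if (Matrix::nnzero(m) == 0) {
    stop_degenerate("term-document matrix is all zero; no space to build")
  }
  k <- as.integer(k)
  sv <- svd(as.matrix(m))

  tol <- max(dim(m)) * .Machine$double.eps * sv$d[[1]]
  k_eff <- min(k, sum(sv$d > tol))
  u <- sv$u[, seq_len(k_eff), drop = FALSE]
  v <- sv$v[, seq_len(k_eff), drop = FALSE]
  d <- sv$d[seq_len(k_eff)]

  # sign convention: largest-|entry| of each term vector made positive
  for (j in seq_len(k_eff)) {
    i_max <- which.max(abs(u[, j]))
    if (u[i_max, j] < 0) {
      u[, j] <- -u[, j]
      v[, j] <- -v[, j]
    }
  }
  rownames(u) <- rownames(m)

  structure(
    list(
      U = u, singular_values = d, V = v, k = k_eff,
      weighting = tdm$weighting, global_weights = tdm$global_weights,
      vocab = tdm$vocab
    ),
    class = "semantic_space"
  )
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(
    "<semantic_space> k = ", x$k, ", ", nrow(x$U), " terms, ",
    nrow(x$V), " documents (", x$weighting, " weighting)\n",
    "singular values: ", paste(signif(head(x$singular_values, 5), 4),
      collapse = ", "
    ),
    if (x$k > 5) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Term vectors of a semantic space
#'
#' Rows of `U_k`, by default scaled by the singular values (`U_k S_k`, the
#' dominant convention for term-term cosines in LSA and the one used by
#' term clustering and medoid assignment).
#'
#' @param space A [build_space()] result.
#' @param scaled Scale columns by the singular values (default TRUE).
#' @param terms Optional character vector restricting (and ordering) rows;
#'   unknown terms raise an error naming them.
#' @return Numeric matrix, rownames = terms.
#' @export
term_vectors <- function(space, scaled = TRUE, terms = NULL) {
  stopifnot(inherits(space, "semantic_space"))
  m <- if (scaled) {
    sweep(space$U, 2, space$singular_values, `*`)
  } else {
    space$U
  }
  rownames(m) <- rownames(space$U)
  if (!is.null(terms)) {
    missing <- setdiff(terms, rownames(m))
    if (length(missing)) {
      stop_invalid(paste0(
        "term(s) not in the semantic space: ",
        paste(missing, collapse = ", ")
      ))
    }
    m <- m[terms, , drop = FALSE]
  }
  m
}

#' Fold a token sequence into the semantic space
#'
#' Projects a new passage into an existing space without refactorizing:
#' returns `S_k^-1 U_k' a`, where `a` is the weighted term vector of
#' in-vocabulary token counts (the same weighting the space was built
#' with). Out-of-vocabulary tokens are ignored; if no token is known the
#' zero vector is returned with attribute `all_oov = TRUE`. By
#' construction, folding in exactly the tokens of a training document
#' reproduces that document's row of `V`.
#'
#' @param space A [build_space()] result.
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @return Numeric k-vector with logical attribute `all_oov`.
#' @export
fold_in <- function(space, tokens) {
  stopifnot(inherits(space, "semantic_space"))
  a <- weighted_count_matrix(space, list(tokens))
  v <- as.numeric(Matrix::crossprod(a, space$U)) / space$singular_values
  structure(v, all_oov = Matrix::nnzero(a) == 0)
}

# sparse T x n matrix of weighted token counts for n token sequences
weighted_count_matrix <- function(space, token_list) {
  terms <- space$vocab$term
  idx <- lapply(token_list, function(t) {
    i <- match(t, terms)
    i[!is.na(i)]
  })
  counts <- Matrix::sparseMatrix(
    i = unlist(idx, use.names = FALSE),
    j = rep.int(seq_along(idx), lengths(idx)),
    x = 1,
    dims = c(length(terms), length(idx))
  )
  if (space$weighting == "raw") {
    return(counts)
  }
  trip <- methods::as(counts, "TsparseMatrix")
  Matrix::sparseMatrix(
    i = trip@i + 1L, j = trip@j + 1L,
    x = log1p(trip@x) * space$global_weights[trip@i + 1L],
    dims = dim(counts)
  )
}

# fold a list of token sequences at once; rows = passages
fold_matrix <- function(space, token_list) {
  a <- weighted_count_matrix(space, token_list)
  proj <- as.matrix(Matrix::crossprod(a, space$U))
  sweep(proj, 2, space$singular_values, `/`)
}

#' Cosine similarity
#'
#' `u . v / (||u|| ||v||)`; if either vector is zero the similarity is
#' defined as 0 ("no similarity"), so all-out-of-vocabulary passages are
#' never assigned anywhere.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_sim(c(1, 2), c(2, 1)) # 0.8
cosine_sim <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(0)
  }
  sum(u * v) / (nu * nv)
}

#' @rdname build_space
#' @param x,object A `semantic_space`.
#' @param ... Unused.
#' @export
tidy.semantic_space <- function(x, ...) {
  tibble(
    dimension = seq_len(x$k),
    singular_value = x$singular_values,
    variance_share = x$singular_values^2 / sum(x$singular_values^2)
  )
}

#' @rdname build_space
#' @export
glance.semantic_space <- function(x, ...) {
  tibble(
    k = x$k, n_terms = nrow(x$U), n_docs = nrow(x$V),
    weighting = x$weighting,
    top_singular_value = x$singular_values[[1]]
  )
}

#' Scree plot of a semantic space
#'
#' @param object A [build_space()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.semantic_space <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$dimension, y = .data$singular_value)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(
      x = "dimension", y = "singular value",
      title = sprintf("Semantic space spectrum (k = %d)", object$k)
    ) +
    theme_minimal()
}

#' Persist a semantic space
#'
#' Writes a directory holding a JSON manifest (k, weighting, vocabulary
#' size) and TSV arrays for singular values, term vectors, and document
#' vectors.
#'
#' @param space A [build_space()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_space <- function(space, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(
      k = space$k, weighting = space$weighting,
      n_terms = nrow(space$U), n_docs = nrow(space$V)
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE
  )
  readr::write_tsv(
    tibble(dimension = seq_len(space$k), sigma = space$singular_values),
    file.path(dir, "singular_values.tsv")
  )
  u <- as_tibble(as.data.frame(space$U), .name_repair = "minimal")
  names(u) <- paste0("dim", seq_len(space$k))
  readr::write_tsv(
    dplyr::bind_cols(tibble(term = rownames(space$U)), u),
    file.path(dir, "term_vectors.tsv")
  )
  v <- as_tibble(as.data.frame(space$V), .name_repair = "minimal")
  names(v) <- paste0("dim", seq_len(space$k))
  readr::write_tsv(v, file.path(dir, "doc_vectors.tsv"))
  invisible(dir)
}
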