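# Clustering-term selection, cosine dissimilarity, and partitioning around
# medoids (PAM) over semantic-space term vectors.

#' Select clustering terms from meaningful responses
#'
#' Terms whose total occurrence count across the meaningful responses is
#' strictly greater than `min_freq` (the "appeared more than 70 times"
#' rule; frequency is token count, not document frequency), excluding the
#' high-frequency stop list and anything outside the semantic-space
#' vocabulary.
#'
#' @param responses Tibble of meaningful responses (needs `text`), a
#'   character vector, or a token list.
#' @param space A [build_space()] result (restricts terms to its
#'   vocabulary); optional.
#' @param min_freq Strict lower frequency bound (default 70).
#' @param stoplist Character vector of excluded terms (default
#'   [lsa_stoplist()]).
#' @return Tibble (`term`, `freq`) in decreasing frequency order; empty
#'   (with a warning) if nothing qualifies.
#' @export
select_cluster_terms <- function(responses, space = NULL, min_freq = 70,
                                 stoplist = lsa_stoplist()) {
  if (min_freq < 1) stop_invalid("`min_freq` must be >= 1")
  toks <- doc_tokens(responses)
  counts <- table(unlist(toks, use.names = FALSE))
  keep <- counts[counts > min_freq]
  terms <- setdiff(names(keep), stoplist)
  if (!is.null(space)) terms <- intersect(terms, space$vocab$term)
  if (length(terms) == 0) {
    warn("no clustering terms exceed `min_freq`; returning empty set")
    return(tibble(term = character(), freq = integer()))
  }
  out <- tibble(term = terms, freq = as.integer(counts[terms]))
  dplyr::arrange(out, dplyr::desc(.data$freq), .data$term)
}

#' Cosine dissimilarity matrix over clustering terms
#'
#' Entry (i, j) is `1 - cosine(t_i, t_j)` over the (scaled) semantic-space
#' term vectors, giving a symmetric matrix with zero diagonal and entries
#' in `[0, 2]`.
#'
#' @param space A [build_space()] result.
#' @param terms Character vector or [select_cluster_terms()] tibble; a
#'   term missing from the space raises an error naming it.
#' @param scaled Use singular-value-scaled term vectors (default TRUE).
#' @return Dense symmetric matrix with term dimnames.
#' @export
build_distance_matrix <- function(space, terms, scaled = TRUE) {
  if (is.data.frame(terms)) terms <- terms$term
  tv <- term_vectors(space, scaled = scaled, terms = terms)
  norms <- sqrt(rowSums(tv^2))
  norms[norms == 0] <- 1 # zero vectors: cosine defined as 0
  cosines <- tcrossprod(tv / norms)
  d <- 1 - cosines
  d[cbind(seq_along(terms), seq_along(terms))] <- 0
  pmin(pmax((d + t(d)) / 2, 0), 2)
}

#' Partition terms around medoids (PAM)
#'
#' Classic PAM on a precomputed dissimilarity matrix: a greedy BUILD phase
#' seeds `k_c` medoids, then the SWAP phase exhaustively tests
#' medoid/non-medoid exchanges, applying the best strictly-improving swap
#' until none remains. Deterministic given the matrix. The boundary
#' `k_c = n` (every term its own medoid, cost 0) is handled directly.
#'
#' @param dist Symmetric dissimilarity matrix with term dimnames (from
#'   [build_distance_matrix()]).
#' @param k_c Number of clusters, `1 <= k_c <= nrow(dist)` (production
#'   default 20 areas of concern).
#' @return Object of class `term_clustering`: `assignment` tibble (`term`,
#'   `cluster`, `is_medoid`, `dist_to_medoid`), `medoids` (character, one
#'   per cluster), total `cost` (sum of distances to medoids), `k`, and
#'   the dissimilarity matrix (kept for [describe_clusters()]).
#' @export
pam_cluster <- function(dist, k_c) {
  n <- nrow(dist)
  terms <- rownames(dist) %||% as.character(seq_len(n))
  if (!is.numeric(k_c) || k_c < 1 || k_c > n) {
    stop_invalid(sprintf("`k_c` must be in [1, %d]", n))
  }
  k_c <- as.integer(k_c)
  if (k_c == n) {
    clustering <- seq_len(n)
    medoid_idx <- seq_len(n)
  } else {
    fit <- cluster::pam(as.dist(dist), k = k_c, diss = TRUE)
    clustering <- as.integer(fit$clustering)
    medoid_idx <- as.integer(fit$id.med)
  }
  d_to_med <- dist[cbind(seq_len(n), medoid_idx[clustering])]
  structure(
    list(
      assignment = tibble(
        term = terms,
        cluster = clustering,
        is_medoid = seq_len(n) %in% medoid_idx,
        dist_to_medoid = as.numeric(d_to_med)
      ),
      medoids = terms[medoid_idx],
      medoid_index = medoid_idx,
      cost = sum(d_to_med),
      k = k_c,
      dist = dist
    ),
    class = "term_clustering"
  )
}

#' @export
print.term_clustering <- function(x, ...) {
  cat(
    "<term_clustering> ", x$k, " clusters over ", nrow(x$assignment),
    " terms, total cost ", signif(x$cost, 5), "\n",
    "medoids: ", paste(head(x$medoids, 8), collapse = ", "),
    if (x$k > 8) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname pam_cluster
#' @param x,object A `term_clustering`.
#' @param ... Unused.
#' @export
tidy.term_clustering <- function(x, ...) x$assignment

#' @rdname pam_cluster
#' @export
glance.term_clustering <- function(x, ...) {
  tibble(
    k = x$k, n_terms = nrow(x$assignment), cost = x$cost,
    mean_dist_to_medoid = x$cost / nrow(x$assignment)
  )
}

#' Cluster-size bar chart
#'
#' @param object A `term_clustering`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.term_clustering <- function(object, ...) {
  sizes <- dplyr::count(object$assignment, .data$cluster)
  sizes$medoid <- object$medoids[sizes$cluster]
  ggplot(sizes, aes(
    x = stats::reorder(.data$medoid, .data$n), y = .data$n
  )) +
    geom_col() +
    coord_flip() +
    labs(x = "cluster (medoid term)", y = "terms", title = "Cluster sizes") +
    theme_minimal()
}

#' Summarize clusters for human labeling
#'
#' For each cluster: its medoid, size, and the `top_m` member terms nearest
#' the medoid -- the raw material a human labeler uses to name the area of
#' concern. Clusters judged to have no discernable semantic meaning can be
#' listed in `exclude`; they are flagged here, dropped from concern tables,
#' but still counted in any demographic/propensity denominators.
#'
#' @param clustering A [pam_cluster()] result.
#' @param top_m Member terms to show per cluster (default 5).
#' @param exclude Integer cluster ids flagged as not meaningful.
#' @return Tibble (`cluster`, `medoid`, `size`, `excluded`, `terms`
#'   list-column, `related_terms` comma-joined preview).
#' @export
describe_clusters <- function(clustering, top_m = 5, exclude = integer()) {
  stopifnot(inherits(clustering, "term_clustering"))
  asg <- clustering$assignment
  purrr::map_dfr(seq_len(clustering$k), function(cl) {
    members <- asg[asg$cluster == cl, ]
    medoid <- clustering$medoids[[cl]]
    others <- members[members$term != medoid, ]
    others <- others[order(others$dist_to_medoid, others$term), ]
    top <- head(others$term, top_m)
    tibble(
      cluster = cl,
      medoid = medoid,
      size = nrow(members),
      excluded = cl %in% exclude,
      terms = list(c(medoid, top)),
      related_terms = paste(top, collapse = ", ")
    )
  })
}
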