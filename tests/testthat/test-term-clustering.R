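# brute-force k-medoids: enumerate all medoid subsets
brute_kmedoids <- function(dist, k) {
  n <- nrow(dist)
  best <- list(cost = Inf)
  combos <- utils::combn(n, k)
  for (j in seq_len(ncol(combos))) {
    med <- combos[, j]
    cost <- sum(apply(dist[, med, drop = FALSE], 1, min))
    if (cost < best$cost - 1e-12) {
      best <- list(cost = cost, medoids = med)
    }
  }
  best
}

test_that("clustering-term selection applies the strict frequency bound and stop list", {
  toy <- c(
    rep("pain", 71), rep("the", 500), rep("knee", 70)
  )
  toy_docs <- paste(toy, collapse = " ")
  sel <- select_cluster_terms(toy_docs, min_freq = 70, stoplist = "the")
  expect_identical(sel$term, "pain")
  expect_identical(sel$freq, 71L)

  expect_warning(
    empty <- select_cluster_terms(character(0), min_freq = 70, stoplist = "the"),
    "no clustering terms"
  )
  expect_identical(nrow(empty), 0L)
  expect_error(select_cluster_terms(toy_docs, min_freq = 0),
    class = "lsaminer_invalid_argument"
  )
})

test_that("distance matrix equals brute-force pairwise cosines on scaled term vectors", {
  docs <- generate_background_docs(120, tiny_tm(), seed = 8)
  vocab <- build_vocabulary(docs)
  space <- build_space(build_term_doc_matrix(docs, vocab), 12)
  terms <- head(vocab$term, 30)
  dm <- build_distance_matrix(space, terms)

  tv <- term_vectors(space, scaled = TRUE, terms = terms)
  for (i in seq_along(terms)) {
    for (j in seq_along(terms)) {
      expect_lt(
        abs(dm[i, j] - (1 - cosine_sim(tv[i, ], tv[j, ]))),
        1e-12
      )
    }
  }
  expect_equal(max(abs(dm - t(dm))), 0)
  expect_equal(unname(diag(dm)), rep(0, 30))
  expect_true(all(dm >= 0 & dm <= 2))
  expect_error(build_distance_matrix(space, c(terms[1], "zzznope")), "zzznope")
})

test_that("identical and opposite term vectors give distances 0 and 2", {
  u <- rbind(
    a = c(1, 0), b = c(1, 0) / sqrt(2), cc = c(-1, 0), d = c(0, 1)
  )
  sp <- fake_space(u, d = c(1, 1))
  dm <- build_distance_matrix(sp, c("a", "b", "cc", "d"), scaled = FALSE)
  expect_equal(dm["a", "b"], 0) # parallel vectors
  expect_equal(dm["a", "cc"], 2) # opposite vectors
  expect_equal(dm["a", "d"], 1) # orthogonal vectors
})

test_that("pam_cluster matches exhaustive enumeration on small instances", {
  # two well-separated groups on a line
  x <- c(0, 0.1, 0.2, 0.3, 10, 10.1, 10.2, 10.3)
  dm <- as.matrix(dist(x))
  rownames(dm) <- colnames(dm) <- paste0("p", letters[1:8])
  cl <- pam_cluster(dm, 2)
  brute <- brute_kmedoids(dm, 2)
  expect_equal(cl$cost, brute$cost, tolerance = 1e-12)
  # partition recovers the two groups exactly (labels arbitrary)
  grp <- cl$assignment$cluster
  expect_length(unique(grp[1:4]), 1)
  expect_length(unique(grp[5:8]), 1)
  expect_false(grp[[1]] == grp[[5]])

  # k = 1: medoid minimizes total distance (direct linear scan; ties allowed)
  cl1 <- pam_cluster(dm, 1)
  expect_equal(cl1$cost, min(rowSums(dm)))
  expect_true(rowSums(dm)[cl1$medoid_index] <= min(rowSums(dm)) + 1e-12)

  # k = n: every term its own medoid, cost 0
  cln <- pam_cluster(dm, 8)
  expect_equal(cln$cost, 0)
  expect_identical(cln$assignment$cluster, 1:8)
  expect_true(all(cln$assignment$is_medoid))

  expect_error(pam_cluster(dm, 9), class = "lsaminer_invalid_argument")
})

test_that("pam stays within 5% of the exhaustive optimum on random instances", {
  worst <- 0
  for (s in 1:25) {
    set.seed(1000 + s)
    n <- sample(4:10, 1)
    k <- sample(1:3, 1)
    pts <- matrix(rnorm(n * 2), n, 2)
    dm <- as.matrix(dist(pts))
    rownames(dm) <- colnames(dm) <- paste0("t", letters[seq_len(n)])
    cl <- pam_cluster(dm, k)
    opt <- brute_kmedoids(dm, k)$cost
    ratio <- if (opt < 1e-12) 1 else cl$cost / opt
    worst <- max(worst, ratio)
    # clusters exhaustive, non-overlapping, medoids self-assigned at 0
    expect_identical(sort(unique(cl$assignment$cluster)), seq_len(k))
    expect_equal(
      cl$assignment$dist_to_medoid[cl$assignment$is_medoid],
      rep(0, k)
    )
  }
  expect_lte(worst, 1.05)
})

test_that("the swap phase never worsens the build-phase cost", {
  for (s in 1:10) {
    set.seed(2000 + s)
    pts <- matrix(rnorm(40), 20, 2)
    dm <- as.matrix(dist(pts))
    build_only <- cluster::pam(as.dist(dm), k = 4, diss = TRUE, do.swap = FALSE)
    build_cost <- sum(dm[cbind(1:20, build_only$id.med[build_only$clustering])])
    full <- pam_cluster(`dimnames<-`(dm, list(paste0("x", 1:20), paste0("x", 1:20))), 4)
    expect_lte(full$cost, build_cost + 1e-12)
  }
})

test_that("describe_clusters summarizes medoids and nearest members", {
  run <- small_run()
  clustering <- run$objects$clustering
  desc <- describe_clusters(clustering, top_m = 5)
  expect_identical(desc$cluster, seq_len(clustering$k))
  expect_identical(desc$medoid, clustering$medoids)
  expect_true(all(lengths(desc$terms) <= 6))

  # planted structure: each topic's exclusive seed terms co-occur in the
  # top-5 neighbourhood of a single cluster for >= 80% of topics
  tm <- run$objects$topic_model
  excl <- exclusive_terms(tm)
  hits <- vapply(unique(excl$topic), function(tp) {
    seeds <- excl$term[excl$topic == tp]
    best <- vapply(desc$terms, function(tt) length(intersect(tt, seeds)), integer(1))
    max(best) >= 4 # medoid + top-5 dominated by this topic's seeds
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # singleton cluster: summary is the medoid alone
  dm <- matrix(c(0, 1.9, 1.9, 1.9, 0, 0.1, 1.9, 0.1, 0), 3, 3)
  rownames(dm) <- colnames(dm) <- c("solo", "m", "n")
  cl <- pam_cluster(dm, 2)
  d2 <- describe_clusters(cl)
  solo_row <- d2[d2$size == 1, ]
  expect_identical(solo_row$terms[[1]], solo_row$medoid)
  expect_identical(solo_row$related_terms, "")
})
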