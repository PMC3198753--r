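test_that("membership requires cosine strictly greater than the threshold", {
  run <- small_run()
  sp <- run$objects$space
  clustering <- run$objects$clustering
  meaningful <- run$objects$split$meaningful

  probe <- meaningful[1:50, ]
  a_low <- assign_responses(sp, probe, clustering, threshold = -0.99)
  expect_gt(nrow(a_low), 0)
  # re-running with the threshold set to an attained cosine drops exactly
  # the memberships at that value: strict inequality, ties excluded
  cut <- a_low$cosine[[1]] # an attained cosine: an exact tie must drop
  a_cut <- assign_responses(sp, probe, clustering, threshold = cut)
  expect_true(all(a_cut$cosine > cut))
  n_at_or_below <- sum(a_low$cosine <= cut)
  expect_identical(nrow(a_low) - nrow(a_cut), n_at_or_below)

  # near-1 threshold unassigns (almost) everything
  a_hi <- assign_responses(sp, probe, clustering, threshold = 0.999999)
  expect_lte(nrow(a_hi), 2)
  expect_error(
    assign_responses(sp, probe, clustering, threshold = 1),
    class = "lsaminer_invalid_argument"
  )
})

test_that("lowering the threshold never removes a membership", {
  run <- small_run()
  probe <- run$objects$split$meaningful[1:80, ]
  a2 <- assign_responses(run$objects$space, probe, run$objects$clustering, 0.2)
  a1 <- assign_responses(run$objects$space, probe, run$objects$clustering, 0.05)
  key2 <- paste(a2$response_id, a2$cluster)
  key1 <- paste(a1$response_id, a1$cluster)
  expect_true(all(key2 %in% key1))
})

test_that("all-out-of-vocabulary responses are never assigned", {
  run <- small_run()
  fake <- tibble::tibble(
    response_id = c("oov1", "oov2"),
    text = c("zzzalpha zzzbeta", "")
  )
  a <- assign_responses(run$objects$space, fake, run$objects$clustering, -0.5)
  expect_identical(nrow(tibble::as_tibble(a)), 0L)
  expect_setequal(attr(a, "unassigned"), c("oov1", "oov2"))
})

test_that("rank_clusters orders by count with id tie-break and reports coverage", {
  asg <- tibble::tibble(
    response_id = c(sprintf("r%02d", 1:19)),
    cluster = rep(c(3L, 2L, 7L), times = c(5, 9, 5)),
    cosine = 0.5
  )
  attr(asg, "n_responses") <- 25
  rk <- rank_clusters(asg)
  expect_identical(rk$cluster, c(2L, 3L, 7L))
  expect_identical(rk$n_responses, c(9L, 5L, 5L))
  expect_identical(rk$rank, 1:3)
  expect_equal(attr(rk, "coverage"), 19 / 25)

  empty <- asg[0, ]
  attr(empty, "n_responses") <- 10
  rk0 <- rank_clusters(empty)
  expect_identical(nrow(rk0), 0L)
  expect_equal(attr(rk0, "coverage"), 0)
})

test_that("concern-table percentages match independent recomputation", {
  # independent spreadsheet-style recomputation on random count tables
  set.seed(77)
  for (rep in 1:5) {
    labels <- paste0("area", letters[1:6])
    counts <- tibble::tibble(
      label = rep(labels, 3),
      stratum = rep(c("total", "s1", "s2"), each = 6),
      n = c(rpois(6, 300), rpois(6, 150), rpois(6, 150))
    )
    tab <- concern_table(counts)
    for (st in c("total", "s1", "s2")) {
      sub <- counts[counts$stratum == st, ]
      two_dec <- floor(10000 * sub$n / sum(sub$n) + 0.5 + 1e-9) / 100
      manual <- floor(10 * two_dec + 0.5 + 1e-9) / 10
      got <- tab[[paste0("pct_", st)]][match(sub$label, tab$label)]
      expect_equal(got, manual)
    }
    # percentages sum to 100 up to rounding slack
    expect_lt(abs(sum(tab$pct_total) - 100), 0.1 * length(labels))
  }

  # degenerate single cluster: 100.0
  one <- concern_table(tibble::tibble(label = "only", stratum = "total", n = 42))
  expect_equal(one$pct_total, 100)
})

test_that("build_concern_table drops unlabeled clusters and validates strata", {
  run <- small_run()
  asg <- run$objects$assignments
  meaningful <- run$objects$split$meaningful
  strata <- stats::setNames(meaningful$panel, meaningful$response_id)
  labels <- stats::setNames(
    c("area_one", NA, "area_three", "area_four"),
    as.character(1:4)
  )
  tab <- build_concern_table(asg, labels, strata)
  expect_setequal(tab$label, c("area_one", "area_three", "area_four"))
  expect_equal(sum(tab$n_total), unname(attr(tab, "totals")["total"]))

  # per-response denominator option
  tab_r <- build_concern_table(asg, labels, strata, denominator = "responses")
  expect_true(all(tab_r$pct_total <= tab$pct_total + 1e-9 |
    tab_r$n_total == tab$n_total))

  # a response without a stratum is an error naming it
  bad <- strata[-1]
  missing_id <- setdiff(unique(asg$response_id), names(bad))
  if (length(missing_id)) {
    expect_error(build_concern_table(asg, labels, bad), missing_id[[1]])
  }
})

test_that("multi-membership happens but stays a minority on synthetic data", {
  run <- small_run()
  expect_lt(attr(run$objects$assignments, "multi_rate"), 0.5)
})
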