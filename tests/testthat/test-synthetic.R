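test_that("generators reject invalid arguments", {
  tm <- tiny_tm()
  expect_error(generate_background_docs(0, tm, seed = 1), "n_docs")
  expect_error(generate_participants(0, seed = 1), class = "lsaminer_invalid_argument")
  p <- generate_participants(5, seed = 1)
  expect_error(
    generate_responses(p, tm, null_rate = 1.5, seed = 1),
    class = "lsaminer_invalid_argument"
  )
  expect_error(
    propensity_config(covariates = list(
      sex = list(levels = c("m", "f"), margins = c(0.6, 0.6), coef = c(0, 1))
    )),
    class = "lsaminer_invalid_config"
  )
  expect_error(
    propensity_config(covariates = list(
      sex = list(levels = c("m", "f"), margins = c(0.5, 0.5), coef = c(1, 0))
    )),
    class = "lsaminer_invalid_config"
  )
})

test_that("generation is bit-identical for a fixed seed", {
  tm <- tiny_tm()
  expect_identical(
    generate_background_docs(100, tm, seed = 9),
    generate_background_docs(100, tm, seed = 9)
  )
  p1 <- generate_participants(500, seed = 9)
  expect_identical(p1, generate_participants(500, seed = 9))
  expect_identical(
    generate_responses(p1, tm, seed = 9),
    generate_responses(p1, tm, seed = 9)
  )
  expect_false(identical(p1, generate_participants(500, seed = 10)))
})

test_that("exclusive-term corpus frequencies match the closed-form mixture expectation", {
  tm <- topic_model(n_topics = 12)
  n_docs <- 5000
  docs <- generate_background_docs(n_docs, tm, seed = 1)
  counts <- table(unlist(tokenize(docs$text)))

  # closed form: a doc involves topic t alone w.p. p1 = P(1 topic)/12, in a
  # pair w.p. p2 = P(2 topics)*2/12; term count | doc length L is
  # Bin(L, alpha * w) (alone) or Bin(L, alpha * w / 2) (pair); L = min + NB.
  p_one <- tm$doc_mix[[1]] / length(tm$labels)
  p_two <- tm$doc_mix[[2]] * 2 / length(tm$labels)
  len <- tm$doc_length
  e_len <- len$min + len$mu
  var_len <- len$mu + len$mu^2 / len$size

  for (lab in tm$labels) {
    d <- tm$topics[[lab]]
    w <- d$prob[d$exclusive]
    q_cases <- rbind(
      c(p = p_one, q = 1), c(p = p_two, q = 0.5),
      c(p = 1 - p_one - p_two, q = 0)
    )
    for (j in seq_along(w)) {
      rate <- tm$alpha * w[[j]] * q_cases[, "q"]
      mu_case <- e_len * rate
      var_case <- e_len * rate * (1 - rate) + var_len * rate^2
      mu <- sum(q_cases[, "p"] * mu_case)
      v <- sum(q_cases[, "p"] * (var_case + mu_case^2)) - mu^2
      expected <- n_docs * mu
      sd3 <- 3 * sqrt(n_docs * v)
      term <- d$term[d$exclusive][[j]]
      obs <- if (term %in% names(counts)) counts[[term]] else 0
      expect_lt(abs(obs - expected), sd3)
      expect_gt(obs, 0) # every exclusive term occurs at this corpus size
    }
  }
})

test_that("participant covariate margins and null coefficients behave as configured", {
  n <- 10000
  cfg0 <- propensity_config(
    intercept = 0,
    covariates = list(
      sex = list(
        levels = c("m", "f"), margins = c(0.7, 0.3), coef = c(0, 0)
      )
    )
  )
  p <- generate_participants(n, cfg0, seed = 3)
  expect_lt(abs(mean(p$responded) - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(p$sex == "f") - 0.3), 3 * sqrt(0.3 * 0.7 / n))

  p_def <- generate_participants(n, propensity_config(), seed = 4)
  cov_def <- propensity_config()$covariates
  for (nm in c("sex", "health", "branch")) {
    m <- cov_def[[nm]]$margins
    for (i in seq_along(m)) {
      obs <- mean(p_def[[nm]] == cov_def[[nm]]$levels[[i]])
      expect_lt(abs(obs - m[[i]]), 3 * sqrt(m[[i]] * (1 - m[[i]]) / n))
    }
  }
})

test_that("planted fair/poor-health effect of log(3) shows up as an empirical odds ratio near 3", {
  p <- generate_participants(10000, propensity_config(), seed = 11)
  tab <- table(
    fair_poor = p$health == "fair_poor",
    responded = p$responded
  )
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
    (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  # marginal (unadjusted) OR of a planted conditional log(3); wide 3-SE band
  expect_gt(or, 2.4)
  expect_lt(or, 3.75)
})

test_that("null-rate boundaries and the default 54.6% rate hold", {
  tm <- tiny_tm()
  p <- generate_participants(20000,
    propensity_config(intercept = 0.5),
    seed = 5
  )

  all_null <- generate_responses(p, tm, null_rate = 1, seed = 5)
  expect_true(all(all_null$truth$is_null))
  expect_true(all(lengths(all_null$truth$topics) == 0))

  none_null <- generate_responses(p, tm, null_rate = 0, seed = 5)
  expect_false(any(none_null$truth$is_null))
  expect_true(all(lengths(none_null$truth$topics) >= 1))

  def <- generate_responses(p, tm, null_rate = 0.546, seed = 5)
  n <- nrow(def$responses)
  expect_gt(n, 5000)
  expect_lt(
    abs(mean(def$truth$is_null) - 0.546),
    3 * sqrt(0.546 * 0.454 / n)
  )
  # null flag true exactly when no topic was planted
  expect_identical(def$truth$is_null, lengths(def$truth$topics) == 0)
})

test_that("expected_response_rate matches the empirical response share", {
  cfg <- propensity_config()
  expected <- expected_response_rate(cfg)
  expect_equal(expected, 0.377, tolerance = 1e-3)
  p <- generate_participants(40000, cfg, seed = 8)
  expect_lt(
    abs(mean(p$responded) - expected),
    3 * sqrt(expected * (1 - expected) / 40000)
  )
})
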