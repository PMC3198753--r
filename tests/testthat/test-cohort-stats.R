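test_that("single-covariate AOR equals the closed-form 2x2 odds ratio", {
  a <- 20; b <- 35; c <- 15; d <- 30
  fit <- fit_propensity(
    records_from_2x2(a, b, c, d),
    covariates = "exposure", ref_levels = list(exposure = "no")
  )
  td <- tidy(fit)
  expect_equal(
    td$aor[td$level == "yes"], (a * d) / (b * c),
    tolerance = 1e-6
  )
  expect_equal(td$aor[td$reference], 1)
  expect_true(td$conf_low[td$level == "yes"] <= td$aor[td$level == "yes"])
  expect_true(td$conf_high[td$level == "yes"] >= td$aor[td$level == "yes"])
})

test_that("Wald intervals cover 1 under outcome-covariate independence", {
  covered <- 0L
  total <- 0L
  for (s in 1:200) {
    set.seed(3000 + s)
    n <- 800
    df <- tibble::tibble(
      responded = runif(n) < 0.3,
      g1 = sample(c("a", "b", "c"), n, replace = TRUE),
      g2 = sample(c("x", "y"), n, replace = TRUE)
    )
    td <- tidy(fit_propensity(df, covariates = c("g1", "g2")))
    lv <- td[!td$reference, ]
    covered <- covered + sum(lv$conf_low <= 1 & lv$conf_high >= 1)
    total <- total + nrow(lv)
  }
  expect_gte(covered / total, 0.93)
})

test_that("planted propensity coefficients are recovered at n = 20,000", {
  cfg <- propensity_config()
  p <- generate_participants(20000, cfg, seed = 17)
  fit <- fit_propensity(p, outcome = "responded")
  td <- tidy(fit)
  fp <- td[td$covariate == "health" & td$level == "fair_poor", ]
  expect_gt(fp$aor, 2.5)
  expect_lt(fp$aor, 3.6)
  # nearly all nonzero planted coefficients land inside their Wald interval
  inside <- logical(0)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    for (i in seq_along(cv$levels)[-1]) {
      row <- td[td$covariate == nm & td$level == cv$levels[[i]], ]
      expect_identical(nrow(row), 1L)
      if (cv$coef[[i]] != 0) {
        inside <- c(
          inside,
          exp(cv$coef[[i]]) >= row$conf_low & exp(cv$coef[[i]]) <= row$conf_high
        )
      }
    }
  }
  expect_gte(mean(inside), 0.9)
})

test_that("singular designs fail loudly, naming the covariate", {
  df <- tibble::tibble(
    responded = rep(c(TRUE, FALSE), 50),
    dup1 = rep(c("p", "q"), each = 50),
    dup2 = rep(c("p", "q"), each = 50)
  )
  expect_error(
    fit_propensity(df, covariates = c("dup1", "dup2")),
    "dup2"
  )
})

test_that("complete-case filtering counts match a brute-force missingness scan", {
  p <- generate_participants(2000, seed = 21)
  p$education[c(5, 99, 1000)] <- NA
  p$health[c(2, 7)] <- NA # kept via explicit missing level
  fit <- fit_propensity(p, outcome = "responded")
  expect_identical(fit$n_dropped, 3L)
  expect_identical(fit$n_used, 1997L)
  expect_identical(glance(fit)$converged, TRUE)
})

test_that("characteristics tables reproduce configured margins", {
  p <- generate_participants(20000, seed = 23)
  tab <- tabulate_characteristics(p, outcome = "responded")
  cfg <- propensity_config()$covariates

  # single-participant degenerate case: 100% in its level
  one <- tabulate_characteristics(p[1, ], covariates = "sex")
  expect_equal(one$pct_all[one$n_all == 1], 100)

  for (st in unique(tab$stratum)) {
    for (cv in c("sex", "rank", "health")) {
      sub <- tab[tab$stratum == st & tab$covariate == cv, ]
      expect_lt(abs(sum(sub$pct_all) - 100), 0.1 * nrow(sub))
      expect_lt(abs(sum(sub$pct_responders) - 100), 0.1 * nrow(sub))
      n_st <- sum(sub$n_all)
      for (i in seq_len(nrow(sub))) {
        m <- cfg[[cv]]$margins[match(sub$level[[i]], cfg[[cv]]$levels)]
        expect_lt(
          abs(sub$pct_all[[i]] / 100 - m),
          3 * sqrt(m * (1 - m) / n_st) + 0.0006 # rounding slack
        )
      }
    }
  }
})

test_that("cohen_kappa matches hand-worked values and its invariants", {
  expect_equal(cohen_kappa(c("x", "y", "x"), c("x", "y", "x"))$kappa, 1)

  # 2x2 agreement table (20, 5; 10, 15): p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c("pos", "pos", "neg", "neg"), times = c(20, 5, 10, 15))
  b <- rep(c("pos", "neg", "pos", "neg"), times = c(20, 5, 10, 15))
  k <- cohen_kappa(a, b)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k$p_observed, 0.7, tolerance = 1e-12)
  expect_equal(k$p_expected, 0.5, tolerance = 1e-12)
  # binary case: both one-vs-rest kappas equal the overall kappa
  expect_equal(k$per_category$kappa, c(0.4, 0.4), tolerance = 1e-12)

  # symmetry and the kappa <= 1 bound on random labelings
  set.seed(41)
  for (i in 1:10) {
    la <- sample(c("u", "v", "w"), 60, replace = TRUE)
    lb <- sample(c("u", "v", "w"), 60, replace = TRUE)
    k1 <- cohen_kappa(la, lb)$kappa
    expect_equal(k1, cohen_kappa(lb, la)$kappa)
    expect_lte(k1, 1)
  }

  # chance agreement: permuted balanced labels give kappa near 0
  set.seed(42)
  base <- rep(c("p", "q"), each = 2000)
  perm <- sample(base)
  expect_lt(abs(cohen_kappa(base, perm)$kappa), 0.05)

  # both raters constant and identical: p_e = 1, kappa defined as 1
  expect_equal(cohen_kappa(c("z", "z", "z"), c("z", "z", "z"))$kappa, 1)

  expect_error(cohen_kappa(c("a", "b"), c("a")), class = "lsaminer_invalid_argument")
  expect_error(cohen_kappa("a", "a"), class = "lsaminer_invalid_argument")
})
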