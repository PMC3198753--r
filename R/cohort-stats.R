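# Cohort statistics: responder characteristics tables, multivariable
# logistic response-propensity models (adjusted odds ratios with Wald
# intervals), and Cohen's kappa against human review.

#' Characteristics table: all vs open-text responders
#'
#' Per survey stratum, column percentages of each covariate level among
#' all participants and among those with a positive outcome (by default,
#' having provided a meaningful open-ended response). One decimal,
#' half-up rounding; each covariate's column sums to 100 up to rounding.
#'
#' @param records Participant tibble (one row per survey record).
#' @param covariates Character vector of covariate columns (default: the
#'   standard demographic set present in the data).
#' @param outcome Logical outcome column name (default `"responded"`).
#' @param stratum Stratum column name (default `"panel"`).
#' @return Long tibble: `stratum`, `covariate`, `level`, `n_all`,
#'   `pct_all`, `n_responders`, `pct_responders`.
#' @export
tabulate_characteristics <- function(records,
                                     covariates = NULL,
                                     outcome = "responded",
                                     stratum = "panel") {
  covariates <- covariates %||%
    intersect(names(default_propensity_covariates()), names(records))
  stopifnot(length(covariates) >= 1, outcome %in% names(records))
  purrr::map_dfr(split(records, records[[stratum]]), function(df) {
    resp <- df[df[[outcome]], , drop = FALSE]
    purrr::map_dfr(covariates, function(cv) {
      lv <- level_order(cv, df[[cv]])
      n_all <- table(factor(df[[cv]], levels = lv))
      n_resp <- table(factor(resp[[cv]], levels = lv))
      tibble(
        stratum = df[[stratum]][[1]],
        covariate = cv,
        level = lv,
        n_all = as.integer(n_all),
        pct_all = pct1(as.integer(n_all), nrow(df)),
        n_responders = as.integer(n_resp),
        pct_responders = pct1(as.integer(n_resp), nrow(resp))
      )
    })
  })
}

# canonical level orders (reference first) for the standard covariates;
# unknown covariates fall back to order of appearance
level_order <- function(covariate, values) {
  defaults <- default_propensity_covariates()
  if (covariate %in% names(defaults)) {
    lv <- defaults[[covariate]]$levels
    c(lv[lv %in% values], setdiff(unique(values), lv))
  } else {
    unique(values)
  }
}

#' Fit the response-propensity logistic model
#'
#' Multivariable maximum-likelihood logistic regression of a binary
#' response outcome on all listed covariates entered simultaneously.
#' Adjusted odds ratios are `exp(coefficient)` with Wald 95% intervals
#' `exp(coefficient +- 1.96 SE)`. Records with missing covariate values
#' are removed (complete-case), except self-rated health, whose missing
#' values are kept as an explicit `"missing"` level. Convergence: relative
#' log-likelihood change below 1e-8 or 100 iterations.
#'
#' @param records Participant tibble.
#' @param covariates Covariate column names (default: the standard
#'   demographic set present in the data).
#' @param outcome Logical outcome column (default `"responded"`).
#' @param ref_levels Optional named list overriding reference levels;
#'   defaults to the canonical reference of each standard covariate.
#' @return Object of class `propensity_fit` wrapping the `glm` fit;
#'   [tidy()] returns the AOR table (reference rows included with AOR
#'   fixed at 1), [glance()] the fit summary.
#' @export
fit_propensity <- function(records, covariates = NULL,
                           outcome = "responded", ref_levels = NULL) {
  covariates <- covariates %||%
    intersect(names(default_propensity_covariates()), names(records))
  stopifnot(length(covariates) >= 1, outcome %in% names(records))

  df <- records[, c(outcome, covariates)]
  if ("health" %in% covariates) {
    df$health[is.na(df$health)] <- "missing"
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  for (cv in covariates) {
    lv <- level_order(cv, df[[cv]])
    if (!is.null(ref_levels[[cv]])) {
      lv <- c(ref_levels[[cv]], setdiff(lv, ref_levels[[cv]]))
    }
    df[[cv]] <- factor(df[[cv]], levels = lv)
  }

  fml <- stats::reformulate(covariates, response = outcome)
  fit <- glm(fml, data = df, family = binomial(),
             control = glm.control(epsilon = 1e-8, maxit = 100))
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    offender <- covariates[vapply(
      covariates, function(cv) any(startsWith(bad, cv)), logical(1)
    )]
    stop_degenerate(paste0(
      "singular design / separation involving covariate(s): ",
      paste(offender, collapse = ", ")
    ))
  }

  structure(
    list(
      fit = fit, covariates = covariates, outcome = outcome,
      n_used = nrow(df), n_dropped = n_dropped
    ),
    class = "propensity_fit"
  )
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(
    "<propensity_fit> ", x$outcome, " ~ ",
    paste(x$covariates, collapse = " + "), "\n",
    "n = ", x$n_used, " (", x$n_dropped, " dropped, incomplete covariates)\n",
    sep = ""
  )
  print(tidy(x), n = 15)
  invisible(x)
}

#' @rdname fit_propensity
#' @param x,object A `propensity_fit`.
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... Unused.
#' @export
tidy.propensity_fit <- function(x, conf_level = 0.95, ...) {
  fit <- x$fit
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map_dfr(x$covariates, function(cv) {
    lv <- levels(fit$model[[cv]])
    nm <- paste0(cv, lv)
    is_ref <- !(nm %in% names(est))
    b <- ifelse(is_ref, 0, est[nm])
    s <- ifelse(is_ref, NA_real_, se[nm])
    tibble(
      covariate = cv,
      level = lv,
      reference = is_ref,
      estimate = unname(b),
      std_error = unname(s),
      aor = exp(unname(b)),
      conf_low = exp(unname(b - z * s)),
      conf_high = exp(unname(b + z * s))
    )
  })
  rows$aor[rows$reference] <- 1
  rows$significant <- !rows$reference &
    (rows$conf_low > 1 | rows$conf_high < 1)
  rows
}

#' @rdname fit_propensity
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble(
    n_used = x$n_used,
    n_dropped = x$n_dropped,
    converged = x$fit$converged,
    df_residual = x$fit$df.residual,
    log_lik = as.numeric(stats::logLik(x$fit)),
    aic = stats::AIC(x$fit)
  )
}

#' Forest plot of adjusted odds ratios
#'
#' @param object A [fit_propensity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.propensity_fit <- function(object, ...) {
  df <- tidy(object)
  df$term <- paste(df$covariate, df$level, sep = ": ")
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot(df, aes(x = .data$aor, y = .data$term)) +
    geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_point() +
    geom_errorbarh(
      aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2, na.rm = TRUE
    ) +
    scale_x_log10() +
    labs(
      x = "adjusted odds ratio (95% Wald CI, log scale)", y = NULL,
      title = "Adjusted odds of open-ended response"
    ) +
    theme_minimal()
}

#' Cohen's kappa between two categorical labelings
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` and chance agreement `p_e` from the product of
#' the marginal label distributions. Per-category one-vs-rest kappas are
#' also computed, the form used when comparing automatic cluster labels
#' with human expert review category by category. If both raters are
#' constant and identical (`p_e = 1`), kappa is defined as 1. Landis-Koch
#' interpretation bands are attached as annotations only.
#'
#' @param labels_a,labels_b Equal-length (>= 2) category sequences over a
#'   common domain.
#' @return Object of class `kappa_agreement`: `kappa`, `p_observed`,
#'   `p_expected`, `n`, `interpretation`, and a `per_category` tibble.
#' @export
#' @examples
#' cohen_kappa(c("x", "x", "y"), c("x", "x", "y"))$kappa # 1
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (length(a) != length(b)) {
    stop_invalid("label sequences must have equal length")
  }
  if (length(a) < 2) stop_invalid("need at least 2 paired labels")
  cats <- sort_c(unique(c(a, b)))
  kap <- kappa_stat(a, b)
  per_cat <- purrr::map_dfr(cats, function(cl) {
    tibble(
      category = cl,
      kappa = kappa_stat(a == cl, b == cl)$kappa
    )
  })
  per_cat$interpretation <- landis_koch(per_cat$kappa)
  structure(
    list(
      kappa = kap$kappa, p_observed = kap$p_o, p_expected = kap$p_e,
      n = length(a), per_category = per_cat,
      interpretation = landis_koch(kap$kappa)
    ),
    class = "kappa_agreement"
  )
}

kappa_stat <- function(a, b) {
  n <- length(a)
  cats <- unique(c(a, b))
  p_o <- mean(a == b)
  p_e <- sum(vapply(
    cats, function(cl) mean(a == cl) * mean(b == cl), numeric(1)
  ))
  k <- if (1 - p_e < .Machine$double.eps) 1 else (p_o - p_e) / (1 - p_e)
  list(kappa = k, p_o = p_o, p_e = p_e)
}

landis_koch <- function(k) {
  cut(k,
    breaks = c(-Inf, 0, 0.2, 0.4, 0.6, 0.8, Inf),
    labels = c(
      "poor", "slight", "fair", "moderate", "substantial", "almost perfect"
    ),
    right = TRUE
  ) |> as.character()
}

#' @export
print.kappa_agreement <- function(x, ...) {
  cat(
    "<kappa_agreement> n = ", x$n, ", kappa = ", signif(x$kappa, 4),
    " (", x$interpretation, "); p_o = ", signif(x$p_observed, 4),
    ", p_e = ", signif(x$p_expected, 4), "\n",
    sep = ""
  )
  print(x$per_category)
  invisible(x)
}

#' @rdname cohen_kappa
#' @param x A `kappa_agreement`.
#' @param ... Unused.
#' @export
tidy.kappa_agreement <- function(x, ...) x$per_category

#' @rdname cohen_kappa
#' @export
glance.kappa_agreement <- function(x, ...) {
  tibble(
    kappa = x$kappa, p_observed = x$p_observed,
    p_expected = x$p_expected, n = x$n,
    interpretation = x$interpretation
  )
}
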