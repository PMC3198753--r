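# Synthetic-cohort generator: topic-structured background documents and
# open-ended responses with planted ground truth, plus participant covariates
# tied to response propensity by a known coefficient vector. This is the
# test-bed standing in for the study's proprietary corpus and cohort data.

default_topic_labels <- function(n_topics) {
  base <- c(
    "illness", "exposure", "exercise", "backpain", "deployment",
    "armsymptoms", "mentalhealth", "weightconcern", "vaccination",
    "anxiety", "surgery", "generalhealth"
  )
  if (n_topics <= length(base)) {
    base[seq_len(n_topics)]
  } else {
    c(base, sprintf("extratopic%02d", seq_len(n_topics - length(base))))
  }
}

#' Planted topic model for synthetic text
#'
#' Defines the generative model behind [generate_background_docs()] and
#' [generate_responses()]: a bag-of-words mixture (word order carries no
#' signal, matching what LSA can see) with
#' \itemize{
#'   \item one term distribution per topic over a topic-specific pool of
#'     `n_exclusive` exclusive terms (holding `excl_weight` of the topic
#'     mass, decaying Zipf-like) plus a few terms from a shared
#'     health-vocabulary pool that overlaps between topics;
#'   \item a background distribution over common function words (Zipf
#'     weights over the shipped clustering stop list), emulating the
#'     high-frequency filler that a real stop list would catch;
#'   \item negative-binomial token counts (short responses, longer
#'     background documents);
#'   \item per-passage topic mixing: a response is about a single topic
#'     with probability `p_single`, otherwise about two.
#' }
#' Default topic count is 12: eleven named areas of concern plus one diffuse
#' general-health topic, matching the granularity at which open-ended health
#' concerns are typically reported.
#'
#' @param n_topics Number of planted topics (default 12).
#' @param n_exclusive Exclusive high-weight terms per topic (default 8,
#'   must be >= 5 so each topic is identifiable).
#' @param n_shared Size of the shared health-term pool topics draw from
#'   (default 20).
#' @param shared_per_topic Shared-pool terms mixed into each topic
#'   (default 4).
#' @param excl_weight Share of a topic's token mass on its exclusive terms
#'   (default 0.8).
#' @param p_single Probability a response is single-topic (default 0.85).
#' @param alpha Topical token share of a passage; the rest is background
#'   filler (default 0.7).
#' @param background Character vector of background filler terms (default:
#'   first 120 words of [lsa_stoplist()]).
#' @param doc_length,response_length Lists `list(mu=, size=, min=)` of
#'   negative-binomial length parameters for background documents (mean 60)
#'   and responses (mean 15 tokens, short free-text answers).
#' @param labels Optional topic labels (lower-case alphabetic).
#' @param seed Seed for the fixed topic/shared-pool composition (default 1;
#'   part of the model definition, not of document generation).
#' @return An object of class `topic_model`.
#' @export
#' @examples
#' tm <- topic_model(n_topics = 3, background = letters)
#' tm$topics[[1]]
topic_model <- function(n_topics = 12,
                        n_exclusive = 8,
                        n_shared = 20,
                        shared_per_topic = 4,
                        excl_weight = 0.8,
                        p_single = 0.85,
                        alpha = 0.7,
                        background = NULL,
                        doc_length = list(mu = 60, size = 5, min = 10),
                        response_length = list(mu = 15, size = 3, min = 3),
                        labels = NULL,
                        seed = 1L) {
  if (n_topics < 1) stop_invalid("`n_topics` must be >= 1")
  if (n_exclusive < 5) {
    stop_invalid("each topic needs >= 5 exclusive terms (`n_exclusive` >= 5)")
  }
  labels <- labels %||% default_topic_labels(n_topics)
  stopifnot(length(labels) == n_topics, !anyDuplicated(labels))

  background <- background %||% utils::head(lsa_stoplist(), 120)
  bg_w <- 1 / seq_along(background)^0.9
  background_dist <- tibble(
    term = background, prob = bg_w / sum(bg_w)
  )

  shared_pool <- paste0("health", sprintf("%02d", seq_len(n_shared)))
  topics <- withr::with_seed(substream_seed(seed, "topic_model"), {
    purrr::map(seq_len(n_topics), function(i) {
      excl <- paste0(labels[[i]], letters[seq_len(n_exclusive)])
      shared <- resample(shared_pool, min(shared_per_topic, n_shared))
      w_ex <- 1 / seq_len(n_exclusive)^0.7
      w_ex <- excl_weight * w_ex / sum(w_ex)
      w_sh <- rep((1 - excl_weight) / length(shared), length(shared))
      tibble(
        term = c(excl, shared),
        prob = c(w_ex, w_sh),
        exclusive = c(rep(TRUE, n_exclusive), rep(FALSE, length(shared)))
      )
    })
  })
  names(topics) <- labels

  out <- structure(
    list(
      topics = topics, labels = labels, background_dist = background_dist,
      p_single = p_single, alpha = alpha, doc_mix = c(0.7, 0.3),
      doc_length = doc_length, response_length = response_length
    ),
    class = "topic_model"
  )
  validate_topic_model(out)
  out
}

validate_topic_model <- function(tm) {
  for (lab in tm$labels) {
    d <- tm$topics[[lab]]
    if (abs(sum(d$prob) - 1) > 1e-9) {
      stop_invalid(sprintf("topic '%s' distribution does not sum to 1", lab))
    }
    if (sum(d$exclusive) < 5) {
      stop_invalid(sprintf("topic '%s' has fewer than 5 exclusive terms", lab))
    }
  }
  if (abs(sum(tm$background_dist$prob) - 1) > 1e-9) {
    stop_invalid("background distribution does not sum to 1")
  }
  invisible(tm)
}

#' @export
print.topic_model <- function(x, ...) {
  cat(
    "<topic_model> ", length(x$labels), " topics, ",
    nrow(x$background_dist), " background terms\n",
    "topics: ", paste(x$labels, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Exclusive seed terms of each planted topic
#'
#' @param tm A [topic_model()].
#' @return Tibble with columns `topic`, `term`.
#' @export
exclusive_terms <- function(tm) {
  purrr::imap_dfr(tm$topics, function(d, lab) {
    tibble(topic = lab, term = d$term[d$exclusive])
  })
}

# draw one bag-of-words passage; topic_ids indexes tm$topics (may be empty)
draw_passage <- function(tm, len, topic_ids) {
  n_topical <- if (length(topic_ids)) rbinom(1, len, tm$alpha) else 0L
  toks <- character(0)
  if (n_topical > 0) {
    picks <- resample(topic_ids, n_topical, replace = TRUE)
    for (ti in unique(picks)) {
      d <- tm$topics[[ti]]
      toks <- c(toks, resample(d$term, sum(picks == ti),
        replace = TRUE, prob = d$prob
      ))
    }
  }
  n_bg <- len - n_topical
  if (n_bg > 0) {
    toks <- c(toks, resample(tm$background_dist$term, n_bg,
      replace = TRUE, prob = tm$background_dist$prob
    ))
  }
  paste(toks, collapse = " ")
}

nbinom_len <- function(n, par) {
  pmax(par$min, rnbinom(n, mu = par$mu, size = par$size) + par$min)
}

#' Generate a background document corpus
#'
#' Draws `n_docs` topic-structured bag-of-words documents from a
#' [topic_model()]: each document is about one or two topics (`doc_mix`),
#' with `alpha` of its tokens topical and the rest background filler.
#' Deterministic for a fixed seed.
#'
#' @param n_docs Number of documents (>= 1).
#' @param tm A [topic_model()].
#' @param seed Integer seed; all randomness in this call derives from it.
#' @return Tibble with columns `doc_id`, `text`.
#' @export
generate_background_docs <- function(n_docs, tm, seed) {
  if (!is.numeric(n_docs) || n_docs < 1) {
    stop_invalid("`n_docs` must be >= 1")
  }
  stopifnot(inherits(tm, "topic_model"))
  n_docs <- as.integer(n_docs)
  withr::with_seed(substream_seed(seed, "background_docs"), {
    lens <- nbinom_len(n_docs, tm$doc_length)
    n_top <- resample(seq_along(tm$doc_mix), n_docs,
      replace = TRUE, prob = tm$doc_mix
    )
    text <- vapply(seq_len(n_docs), function(i) {
      draw_passage(tm, lens[[i]], resample(tm$labels, n_top[[i]]))
    }, character(1))
    tibble(doc_id = sprintf("doc%06d", seq_len(n_docs)), text = text)
  })
}

# --- participant covariates and response propensity -------------------------

#' Response-propensity configuration
#'
#' Covariate level sets, marginal category probabilities, and log-odds
#' coefficients (reference level first, coefficient 0) driving the planted
#' logistic model for whether a participant writes anything in the
#' open-ended field. Defaults mirror a large military-cohort setting: the
#' marginal mix of each covariate follows the Panel 1 baseline column of the
#' published characteristics table, the coefficient pattern follows the
#' published adjusted-odds table (e.g. active duty ~ log 1.5), and fair/poor
#' self-rated health is fixed at log(3) -- the dominant, roughly threefold
#' odds effect. The intercept is calibrated so the expected any-response
#' rate over the covariate mixture is 37.7% of surveys
#' (see [expected_response_rate()]).
#'
#' @param intercept Log-odds intercept.
#' @param covariates Named list; each element is
#'   `list(levels=, margins=, coef=)` with margins summing to 1 and
#'   `coef[1] == 0` (reference level). Defaults described above.
#' @return Object of class `propensity_config`.
#' @export
propensity_config <- function(intercept = -0.883608, covariates = NULL) {
  covariates <- covariates %||% default_propensity_covariates()
  out <- structure(
    list(intercept = intercept, covariates = covariates),
    class = "propensity_config"
  )
  validate_propensity_config(out)
  out
}

default_propensity_covariates <- function() {
  cov <- function(levels, margins, coef) {
    list(levels = levels, margins = margins / sum(margins), coef = coef)
  }
  list(
    sex = cov(
      c("male", "female"), c(0.732, 0.268), c(0, log(1.07))
    ),
    birth_year = cov(
      c("before_1960", "y1960_1969", "y1970_1979", "y1980_later"),
      c(0.216, 0.379, 0.346, 0.059),
      c(0, log(0.83), log(0.65), log(0.52))
    ),
    education = cov(
      c("hs_or_less", "some_college", "bachelor", "advanced"),
      c(0.489, 0.255, 0.165, 0.091),
      c(0, log(1.03), log(1.07), log(1.07))
    ),
    marital = cov(
      c("married", "not_married"), c(0.631, 0.369), c(0, log(1.09))
    ),
    race_ethnicity = cov(
      c("white_nonhisp", "black_nonhisp", "other"),
      c(0.696, 0.138, 0.166),
      c(0, log(0.71), log(0.95))
    ),
    deployed = cov(
      c("no", "yes"), c(0.575, 0.425), c(0, log(0.88))
    ),
    rank = cov(
      c("enlisted", "officer"), c(0.770, 0.230), c(0, log(1.07))
    ),
    component = cov(
      c("reserve_guard", "active"), c(0.430, 0.570), c(0, log(1.50))
    ),
    branch = cov(
      c("air_force", "army", "navy_coastguard", "marines"),
      c(0.290, 0.474, 0.185, 0.051),
      c(0, log(1.30), log(1.26), log(1.42))
    ),
    occupation = cov(
      c("other", "combat", "healthcare"),
      c(0.699, 0.200, 0.101),
      c(0, log(1.07), log(0.90))
    ),
    health = cov(
      c("verygood_excellent", "good", "fair_poor", "missing"),
      c(0.590, 0.303, 0.077, 0.030),
      c(0, log(1.55), log(3), 0)
    )
  )
}

validate_propensity_config <- function(cfg) {
  stopifnot(is.numeric(cfg$intercept), length(cfg$covariates) >= 1)
  for (nm in names(cfg$covariates)) {
    cv <- cfg$covariates[[nm]]
    if (length(cv$levels) != length(cv$margins) ||
      length(cv$levels) != length(cv$coef)) {
      abort(
        sprintf("covariate '%s': levels/margins/coef lengths differ", nm),
        class = "lsaminer_invalid_config"
      )
    }
    if (abs(sum(cv$margins) - 1) > 1e-8) {
      abort(
        sprintf("covariate '%s': margins do not sum to 1", nm),
        class = "lsaminer_invalid_config"
      )
    }
    if (cv$coef[[1]] != 0) {
      abort(
        sprintf("covariate '%s': reference level must have coefficient 0", nm),
        class = "lsaminer_invalid_config"
      )
    }
  }
  invisible(cfg)
}

#' @export
print.propensity_config <- function(x, ...) {
  cat(
    "<propensity_config> intercept ", format(x$intercept), ", ",
    length(x$covariates), " covariates: ",
    paste(names(x$covariates), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Expected response rate under a propensity configuration
#'
#' Exact expectation of the response probability over the configured
#' covariate mixture, computed by enumerating the joint distribution of the
#' linear predictor (covariates are independent, so the enumeration is a
#' sequential convolution).
#'
#' @param cfg A [propensity_config()].
#' @return A single probability.
#' @export
expected_response_rate <- function(cfg) {
  eta <- cfg$intercept
  p <- 1
  for (cv in cfg$covariates) {
    eta <- as.vector(outer(eta, cv$coef, `+`))
    p <- as.vector(outer(p, cv$margins, `*`))
  }
  sum(p * plogis(eta))
}

#' Generate participant covariates and response flags
#'
#' Each participant receives independent covariates drawn from the
#' configured margins, a survey stratum (panel), and a `responded` flag
#' drawn Bernoulli with probability
#' `plogis(intercept + sum of level coefficients)`. The realized linear
#' predictor is retained (`propensity`) as ground truth.
#'
#' @param n Number of participants (>= 1).
#' @param cfg A [propensity_config()].
#' @param seed Integer seed.
#' @param panel_margins Named probabilities of the survey strata
#'   (default: baseline/follow-up/second-panel mix of the motivating cohort).
#' @return Tibble with `participant_id`, `panel`, one column per covariate,
#'   `propensity` (response probability) and `responded` (logical).
#' @export
generate_participants <- function(n, cfg = propensity_config(), seed = 1L,
                                  panel_margins = c(
                                    p1_baseline = 0.472,
                                    p1_followup = 0.337,
                                    p2_baseline = 0.191
                                  )) {
  if (!is.numeric(n) || n < 1) stop_invalid("`n` must be >= 1")
  validate_propensity_config(cfg)
  n <- as.integer(n)
  panel_margins <- panel_margins / sum(panel_margins)
  withr::with_seed(substream_seed(seed, "participants"), {
    out <- tibble(
      participant_id = sprintf("p%07d", seq_len(n)),
      panel = resample(names(panel_margins), n,
        replace = TRUE, prob = panel_margins
      )
    )
    eta <- rep(cfg$intercept, n)
    for (nm in names(cfg$covariates)) {
      cv <- cfg$covariates[[nm]]
      idx <- sample.int(length(cv$levels), n, replace = TRUE, prob = cv$margins)
      out[[nm]] <- cv$levels[idx]
      eta <- eta + cv$coef[idx]
    }
    out$propensity <- plogis(eta)
    out$responded <- runif(n) < out$propensity
    out
  })
}

# Surface forms of null responses as participants actually type them; each
# normalizes into the shipped pattern bank. A separate "novel" bank simulates
# null patterns the analyst has not yet catalogued.
null_surface_bank <- c(
  "No", "no", "NO", "No.", "no.", "N/A", "n/a", "NA", "N.A.", "na",
  "None", "none", "None.", "NONE", "Nothing", "nothing", "Nope", "nope",
  "Nothing to add", "nothing to add.", "Nothing to report.",
  "I have nothing to say", "I have no concerns.", "No comment", "no comments",
  "No concerns", "no concerns.", "No health concerns", "No issues",
  "no problems", "Not at this time.", "None at this time", "Not applicable",
  "not really", "Nothing else.", "Nothing further", "nothing more",
  "No additional comments.", "All good", "I'm good", "I am fine", "ok",
  "OK", "Okay", "fine", "Fine.", "See above", "same as above", "x", "XX"
)

novel_null_bank <- c(
  "zilch", "nada", "all set thanks", "negative.", "zero concerns",
  "nothing springs to mind", "can't think of anything", "no worries here"
)

#' Generate open-ended responses with planted ground truth
#'
#' Participants with `responded = TRUE` each produce one response: with
#' probability `null_rate` a meaningless string drawn from a bank of typed
#' null forms ("No.", "N/A", ...), otherwise a topic-structured token
#' sequence from the [topic_model()] (single topic with probability
#' `p_single`, else two). A fraction `novel_null_frac` of null responses is
#' drawn from null strings deliberately absent from the shipped pattern
#' bank, to exercise the filter's false-meaningful path.
#'
#' @param participants Tibble from [generate_participants()].
#' @param tm A [topic_model()].
#' @param null_rate Probability a response is meaningless, in `[0, 1]`
#'   (default 0.546, the share observed in the motivating study).
#' @param seed Integer seed.
#' @param novel_null_frac Fraction of null responses drawn from patterns
#'   outside the shipped bank (default 0).
#' @return List with `responses` (tibble: `response_id`, `participant_id`,
#'   `panel`, `text`) and `truth` (tibble: `response_id`, `is_null`,
#'   `topics` list-column, empty for null responses).
#' @export
generate_responses <- function(participants, tm, null_rate = 0.546,
                               seed = 1L, novel_null_frac = 0) {
  stopifnot(inherits(tm, "topic_model"))
  if (!is.numeric(null_rate) || null_rate < 0 || null_rate > 1) {
    stop_invalid("`null_rate` must be in [0, 1]")
  }
  responders <- dplyr::filter(participants, .data$responded)
  n <- nrow(responders)
  withr::with_seed(substream_seed(seed, "responses"), {
    is_null <- runif(n) < null_rate
    lens <- nbinom_len(n, tm$response_length)
    single <- runif(n) < tm$p_single
    text <- character(n)
    topics <- vector("list", n)
    for (i in seq_len(n)) {
      if (is_null[[i]]) {
        bank <- if (novel_null_frac > 0 && runif(1) < novel_null_frac) {
          novel_null_bank
        } else {
          null_surface_bank
        }
        text[[i]] <- resample(bank, 1)
        topics[[i]] <- character(0)
      } else {
        tp <- resample(tm$labels, if (single[[i]]) 1L else 2L)
        topics[[i]] <- tp
        text[[i]] <- draw_passage(tm, lens[[i]], tp)
      }
    }
    responses <- tibble(
      response_id = sprintf("r%07d", seq_len(n)),
      participant_id = responders$participant_id,
      panel = responders$panel,
      text = text
    )
    truth <- tibble(
      response_id = responses$response_id,
      is_null = is_null,
      topics = topics
    )
    list(responses = responses, truth = truth)
  })
}
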