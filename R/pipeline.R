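# End-to-end orchestration: simulate -> prep -> space -> filter -> cluster
# -> assign -> tabulate -> stats, as a configured, logged, reproducible run
# with every intermediate artifact persisted.

#' Pipeline run configuration
#'
#' Bundles every tunable of a synthetic end-to-end run. The analysis
#' defaults are the production constants of the motivating study design:
#' k = 300 semantic dimensions, clustering terms appearing more than 70
#' times, 20 clusters, cosine threshold 0.2, and a 54.6% null-response
#' rate. Corpus sizes default to the desk-scale synthetic conditions
#' (5,000 background documents; participants sized so that roughly 10,000
#' open-ended responses are expected at the configured response rate).
#' Note k is clamped to the corpus rank at run time when the synthetic
#' vocabulary is smaller than k (see [run_pipeline()]).
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_docs Background documents to simulate.
#' @param n_participants Participants to simulate.
#' @param n_topics Planted topics (default 12).
#' @param null_rate Meaningless-response probability (default 0.546).
#' @param novel_null_frac Share of null responses outside the shipped
#'   pattern bank (default 0).
#' @param k Semantic-space dimensions (default 300).
#' @param min_freq Strict clustering-term frequency bound (default 70).
#' @param k_c Number of clusters (default 20).
#' @param threshold Strict cosine assignment threshold (default 0.2).
#' @param weighting Term-document weighting (default `"log_entropy"`).
#' @param top_m Terms per cluster in summaries (default 5).
#' @param out_dir Run directory for persisted artifacts (default: a fresh
#'   directory under `tempdir()`).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1L,
                       n_docs = 5000L,
                       n_participants = 26500L,
                       n_topics = 12L,
                       null_rate = 0.546,
                       novel_null_frac = 0,
                       k = 300L,
                       min_freq = 70L,
                       k_c = 20L,
                       threshold = 0.2,
                       weighting = "log_entropy",
                       top_m = 5L,
                       out_dir = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_docs = as.integer(n_docs),
    n_participants = as.integer(n_participants),
    n_topics = as.integer(n_topics), null_rate = as.numeric(null_rate),
    novel_null_frac = as.numeric(novel_null_frac), k = as.integer(k),
    min_freq = as.integer(min_freq), k_c = as.integer(k_c),
    threshold = as.numeric(threshold), weighting = weighting,
    top_m = as.integer(top_m), out_dir = out_dir
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Desk-scale planted-topic recovery configuration
#'
#' The reference synthetic operating point for validating the whole
#' pipeline against ground truth: 5,000 background documents, 26,500
#' participants (about 10,000 open-ended responses at the configured
#' 37.7% response rate), 12 planted topics, k = 50 semantic dimensions,
#' 12 clusters, cosine threshold 0.2, null rate 0.546. Under this
#' configuration the planted single-topic labels are recoverable
#' (recovery rate and adjusted Rand index both expected above 0.8).
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [run_config()].
#' @return A [run_config()].
#' @export
planted_recovery_config <- function(seed = 20011001L, ...) {
  run_config(
    seed = seed, n_docs = 5000L, n_participants = 26500L,
    n_topics = 12L, k = 50L, k_c = 12L, threshold = 0.2,
    null_rate = 0.546, ...
  )
}

validate_run_config <- function(cfg) {
  stopifnot(
    cfg$n_docs >= 1, cfg$n_participants >= 1, cfg$n_topics >= 1,
    cfg$null_rate >= 0, cfg$null_rate <= 1,
    cfg$k >= 1, cfg$min_freq >= 1, cfg$k_c >= 1,
    cfg$threshold > -1, cfg$threshold < 1
  )
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in setdiff(names(x), "out_dir")) {
    cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Stage-count percentage summary
#'
#' One-decimal, half-up percentages for the standard funnel: any-response
#' share of surveys, meaningless and meaningful shares of responses,
#' meaningful share of all surveys, and assigned share of meaningful
#' responses. Zero denominators yield `NA` (undefined), never an error.
#'
#' @param n_surveys,n_responses,n_meaningless,n_meaningful,n_assigned
#'   Stage counts (responses = surveys with any open-ended response;
#'   assigned = meaningful responses with at least one cluster).
#' @return Tibble (`metric`, `numerator`, `denominator`, `pct`).
#' @export
#' @examples
#' summarize_counts(163159, 61507, 33591, 27916, 24181)
summarize_counts <- function(n_surveys, n_responses, n_meaningless,
                             n_meaningful, n_assigned) {
  tibble(
    metric = c(
      "any_response_of_surveys", "meaningless_of_responses",
      "meaningful_of_responses", "meaningful_of_surveys",
      "assigned_of_meaningful"
    ),
    numerator = c(
      n_responses, n_meaningless, n_meaningful, n_meaningful, n_assigned
    ),
    denominator = c(
      n_surveys, n_responses, n_responses, n_surveys, n_meaningful
    ),
    pct = pct1(.data$numerator, .data$denominator)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = "lsaminer_pipeline_error", parent = e
    )
  })
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> prep -> space -> filter -> cluster -> assign ->
#' tabulate -> stats under one configuration, persisting every
#' intermediate artifact into the run directory (TSV/MTX/JSON), and
#' returns a report whose counts mirror the standard results funnel:
#' surveys, any-response, meaningless, meaningful, assigned, coverage.
#' Identical config and seed give byte-identical persisted reports.
#'
#' Because the ground truth of the synthetic cohort is known, the report
#' also evaluates planted-topic recovery: clusters are auto-labeled by the
#' majority cluster of each topic's exclusive seed terms, `recovery_rate`
#' is the share of single-topic meaningful responses assigned to their
#' topic's cluster, and `ari` is the adjusted Rand index between best
#' (highest-cosine) cluster and planted topic over assigned single-topic
#' responses (multi-topic responses are excluded from both).
#'
#' If `k` exceeds the rank bound `min(T, D)` of the simulated corpus it is
#' clamped with a warning (`k_used` in the report). If no clustering term
#' survives the frequency bound or fewer terms than `k_c` remain (e.g. at
#' `null_rate = 1`), clustering and assignment are skipped with a warning
#' and the report carries zero counts for those stages.
#'
#' @param cfg A [run_config()].
#' @param keep_objects Attach in-memory stage objects (space, clustering,
#'   assignments, ...) to the returned report as `$objects` (default TRUE;
#'   the persisted JSON never includes them).
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(cfg = run_config(), keep_objects = TRUE) {
  validate_run_config(cfg)
  out_dir <- cfg$out_dir %||% tempfile("lsaminer-run-")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(out_dir, "config.json"))

  # -- simulate ------------------------------------------------------------
  sim <- run_stage("simulate", {
    tm <- topic_model(n_topics = cfg$n_topics)
    pc <- propensity_config()
    participants <- generate_participants(cfg$n_participants, pc, cfg$seed)
    resp <- generate_responses(
      participants, tm,
      null_rate = cfg$null_rate, seed = cfg$seed,
      novel_null_frac = cfg$novel_null_frac
    )
    docs <- generate_background_docs(cfg$n_docs, tm, cfg$seed)
    readr::write_tsv(participants, file.path(out_dir, "participants.tsv"))
    readr::write_tsv(resp$responses, file.path(out_dir, "responses.tsv"))
    readr::write_lines(docs$text, file.path(out_dir, "background_docs.txt"))
    jsonlite::write_json(
      resp$truth, file.path(out_dir, "ground_truth.json"),
      auto_unbox = FALSE, digits = NA
    )
    list(tm = tm, pc = pc, participants = participants,
         responses = resp$responses, truth = resp$truth, docs = docs)
  })

  # -- prep: responses join the space corpus alongside background docs ----
  tdm <- run_stage("prep", {
    corpus <- c(sim$docs$text, sim$responses$text)
    vocab <- build_vocabulary(corpus)
    tdm <- build_term_doc_matrix(corpus, vocab, weighting = cfg$weighting)
    write_term_doc_matrix(tdm, out_dir)
    tdm
  })

  # -- space ---------------------------------------------------------------
  space <- run_stage("space", {
    k_max <- min(dim(tdm$matrix))
    k_used <- cfg$k
    if (k_used > k_max) {
      warn(sprintf(
        "k = %d exceeds corpus rank bound %d; using k = %d",
        cfg$k, k_max, k_max
      ))
      k_used <- k_max
    }
    space <- build_space(tdm, k_used)
    write_space(space, file.path(out_dir, "space"))
    space
  })

  # -- filter --------------------------------------------------------------
  split <- run_stage("filter", {
    patterns <- read_null_patterns()
    split <- split_responses(sim$responses, patterns)
    readr::write_tsv(split$counts, file.path(out_dir, "filter_counts.tsv"))
    split
  })

  # -- cluster -------------------------------------------------------------
  clust <- run_stage("cluster", {
    terms <- select_cluster_terms(
      split$meaningful, space,
      min_freq = cfg$min_freq, stoplist = lsa_stoplist()
    )
    if (nrow(terms) < cfg$k_c) {
      warn(sprintf(
        "only %d clustering terms for k_c = %d; skipping clustering",
        nrow(terms), cfg$k_c
      ))
      NULL
    } else {
      dist <- build_distance_matrix(space, terms)
      clustering <- pam_cluster(dist, cfg$k_c)
      jsonlite::write_json(
        list(
          medoids = clustering$medoids, cost = clustering$cost,
          assignment = clustering$assignment
        ),
        file.path(out_dir, "clustering.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(terms = terms, clustering = clustering)
    }
  })

  # -- assign + tabulate ---------------------------------------------------
  assigned <- NULL
  ranking <- NULL
  concern <- NULL
  eval_res <- NULL
  if (!is.null(clust)) {
    assigned <- run_stage("assign", {
      a <- assign_responses(
        space, split$meaningful, clust$clustering,
        threshold = cfg$threshold
      )
      readr::write_tsv(as_tibble(a), file.path(out_dir, "assignments.tsv"))
      a
    })
    ranking <- run_stage("assign", rank_clusters(assigned))
    eval_res <- run_stage(
      "tabulate",
      evaluate_recovery(assigned, sim$truth, sim$tm, clust$clustering)
    )
    concern <- run_stage("tabulate", {
      labels <- eval_res$cluster_labels
      strata <- setNames(split$meaningful$panel, split$meaningful$response_id)
      summaries <- describe_clusters(clust$clustering, top_m = cfg$top_m)
      related <- setNames(
        summaries$related_terms[match(names(labels), summaries$cluster)],
        unname(labels)
      )
      tab <- build_concern_table(
        assigned,
        labels = labels, strata = strata, related_terms = related
      )
      readr::write_tsv(as_tibble(tab), file.path(out_dir, "concern_table.tsv"))
      tab
    })
  }

  # -- stats ---------------------------------------------------------------
  stats_res <- run_stage("stats", {
    fit <- fit_propensity(sim$participants, outcome = "responded")
    characteristics <- tabulate_characteristics(
      sim$participants,
      outcome = "responded"
    )
    readr::write_tsv(tidy(fit), file.path(out_dir, "aor.tsv"))
    readr::write_tsv(
      characteristics, file.path(out_dir, "characteristics.tsv")
    )
    list(fit = fit, characteristics = characteristics)
  })

  counts <- list(
    n_surveys = nrow(sim$participants),
    n_responses = nrow(sim$responses),
    n_meaningless = split$counts$n_meaningless,
    n_meaningful = split$counts$n_meaningful,
    n_clustering_terms = if (is.null(clust)) 0L else nrow(clust$terms),
    n_assigned = if (is.null(assigned)) {
      0L
    } else {
      as.integer(dplyr::n_distinct(assigned$response_id))
    }
  )
  summary <- summarize_counts(
    counts$n_surveys, counts$n_responses, counts$n_meaningless,
    counts$n_meaningful, counts$n_assigned
  )

  report <- structure(
    list(
      config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
      k_used = space$k,
      counts = counts,
      summary = summary,
      ranking = if (is.null(ranking)) NULL else as_tibble(ranking),
      coverage = if (is.null(ranking)) NA_real_ else attr(ranking, "coverage"),
      multi_rate = if (is.null(assigned)) {
        NA_real_
      } else {
        attr(assigned, "multi_rate")
      },
      concern = if (is.null(concern)) NULL else as_tibble(concern),
      aor = tidy(stats_res$fit),
      eval = if (is.null(eval_res)) {
        NULL
      } else {
        eval_res[c("recovery_rate", "ari", "n_single_topic")]
      },
      out_dir = out_dir
    ),
    class = "pipeline_report"
  )
  jsonlite::write_json(
    report[setdiff(names(report), "out_dir")],
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  if (keep_objects) {
    report$objects <- list(
      topic_model = sim$tm, participants = sim$participants,
      responses = sim$responses, truth = sim$truth, tdm = tdm,
      space = space, split = split,
      terms = if (is.null(clust)) NULL else clust$terms,
      clustering = if (is.null(clust)) NULL else clust$clustering,
      assignments = assigned, fit = stats_res$fit,
      characteristics = stats_res$characteristics,
      cluster_labels = if (is.null(eval_res)) NULL else eval_res$cluster_labels
    )
  }
  report
}

# map each planted topic to the cluster holding most of its exclusive seed
# terms, then score single-topic responses against that mapping
evaluate_recovery <- function(assigned, truth, tm, clustering) {
  excl <- exclusive_terms(tm)
  asg <- clustering$assignment
  excl$cluster <- asg$cluster[match(excl$term, asg$term)]
  map <- excl |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::count(.data$topic, .data$cluster) |>
    dplyr::group_by(.data$topic) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  topic_to_cluster <- setNames(map$cluster, map$topic)
  # labels: cluster -> topic name where a topic claims it (first wins)
  cluster_labels <- setNames(
    map$topic[!duplicated(map$cluster)],
    as.character(map$cluster[!duplicated(map$cluster)])
  )

  single <- truth[!truth$is_null & lengths(truth$topics) == 1, ]
  single$topic <- vapply(single$topics, `[[`, character(1), 1)
  single$expected_cluster <- unname(topic_to_cluster[single$topic])

  memb <- as_tibble(assigned)
  best <- memb |>
    dplyr::group_by(.data$response_id) |>
    dplyr::slice_max(.data$cosine, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  hit_tbl <- memb |>
    dplyr::inner_join(
      single[, c("response_id", "expected_cluster")],
      by = "response_id"
    ) |>
    dplyr::filter(.data$cluster == .data$expected_cluster)
  recovery_rate <- if (nrow(single)) {
    dplyr::n_distinct(hit_tbl$response_id) / nrow(single)
  } else {
    NA_real_
  }

  scored <- dplyr::inner_join(
    best, single[, c("response_id", "topic")], by = "response_id"
  )
  ari <- if (nrow(scored) > 1) {
    mclust::adjustedRandIndex(scored$cluster, scored$topic)
  } else {
    NA_real_
  }
  list(
    recovery_rate = recovery_rate, ari = ari,
    n_single_topic = nrow(single),
    topic_to_cluster = topic_to_cluster, cluster_labels = cluster_labels
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(
    "  surveys ", x$counts$n_surveys,
    " | responses ", x$counts$n_responses,
    " | meaningless ", x$counts$n_meaningless,
    " | meaningful ", x$counts$n_meaningful,
    " | assigned ", x$counts$n_assigned, "\n",
    sep = ""
  )
  print(x$summary)
  if (!is.null(x$eval)) {
    cat(
      "  planted-topic recovery ", signif(x$eval$recovery_rate, 4),
      ", ARI ", signif(x$eval$ari, 4),
      " over ", x$eval$n_single_topic, " single-topic responses\n",
      sep = ""
    )
  }
  cat("  artifacts: ", x$out_dir, "\n", sep = "")
  invisible(x)
}
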