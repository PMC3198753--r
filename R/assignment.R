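# Cosine-threshold assignment of meaningful responses to cluster medoids,
# cluster ranking, and area-of-concern tables.

#' Assign responses to clusters by medoid cosine
#'
#' Each meaningful response is folded into the semantic space and compared
#' with every cluster medoid's (scaled) term vector; the response joins a
#' cluster iff the cosine is strictly greater than `threshold`. Membership
#' is multi-label: a response can join zero, one, or several clusters.
#' All-out-of-vocabulary responses fold to the zero vector (cosine 0 by
#' convention) and are never assigned.
#'
#' @param space A [build_space()] result.
#' @param responses Tibble of meaningful responses (`response_id`, `text`).
#' @param clustering A [pam_cluster()] result.
#' @param threshold Strict cosine threshold in `(-1, 1)` (default 0.2).
#' @return Object of class `assignment_table`: a tibble (`response_id`,
#'   `cluster`, `cosine`) with one row per membership, plus attributes
#'   `n_responses`, `unassigned` (ids with no membership), `threshold`,
#'   and `multi_rate` (share of responses holding > 1 membership).
#' @export
assign_responses <- function(space, responses, clustering, threshold = 0.2) {
  stopifnot(inherits(space, "semantic_space"),
            inherits(clustering, "term_clustering"))
  if (!is.numeric(threshold) || threshold <= -1 || threshold >= 1) {
    stop_invalid("`threshold` must lie in (-1, 1)")
  }
  rv <- fold_matrix(space, tokenize(responses$text)) # n x k
  mv <- term_vectors(space, scaled = TRUE, terms = clustering$medoids)
  mn <- sqrt(rowSums(mv^2))
  rn <- sqrt(rowSums(rv^2))
  cosines <- (rv %*% t(mv)) / (pmax(rn, .Machine$double.xmin) %o% mn)
  # zero fold-in (all tokens out of vocabulary): never assigned anywhere
  cosines[rn == 0, ] <- -Inf

  hit <- which(cosines > threshold, arr.ind = TRUE)
  out <- tibble(
    response_id = responses$response_id[hit[, 1]],
    cluster = as.integer(hit[, 2]),
    cosine = cosines[hit]
  )
  out <- dplyr::arrange(out, .data$response_id, .data$cluster)
  per_resp <- table(factor(out$response_id, levels = responses$response_id))
  structure(
    out,
    class = c("assignment_table", class(out)),
    n_responses = nrow(responses),
    unassigned = responses$response_id[per_resp == 0],
    threshold = threshold,
    multi_rate = if (nrow(responses)) mean(per_resp > 1) else 0
  )
}

#' Rank clusters by response membership
#'
#' Descending response count, ties broken by lower cluster id. Coverage --
#' the fraction of meaningful responses holding at least one membership --
#' is attached as attribute `coverage` and printed.
#'
#' @param assignments An [assign_responses()] result (or any tibble with
#'   `response_id` and `cluster`).
#' @return Tibble (`rank`, `cluster`, `n_responses`) with attribute
#'   `coverage`.
#' @export
rank_clusters <- function(assignments) {
  n_total <- attr(assignments, "n_responses") %||% NA_integer_
  counts <- assignments |>
    dplyr::distinct(.data$response_id, .data$cluster) |>
    dplyr::count(.data$cluster, name = "n_responses") |>
    dplyr::arrange(dplyr::desc(.data$n_responses), .data$cluster)
  counts$rank <- seq_len(nrow(counts))
  counts <- counts[, c("rank", "cluster", "n_responses")]
  coverage <- if (!is.na(n_total) && n_total > 0) {
    dplyr::n_distinct(assignments$response_id) / n_total
  } else {
    0
  }
  structure(counts, coverage = coverage)
}

#' Area-of-concern table from per-cluster counts
#'
#' The arithmetic core shared by [build_concern_table()]: given long
#' counts (one row per labeled area and stratum, plus the `"total"`
#' stratum), computes within-stratum percentages of the table's total
#' assignment count, rounded half-up to one decimal -- the convention of
#' published concern tables, whose listed counts sum exactly to the
#' table's n.
#'
#' @param counts Tibble with columns `label`, `stratum`, `n`.
#' @param related_terms Optional named character vector (label ->
#'   annotation) shown alongside each area.
#' @return Object of class `concern_table`: a wide tibble with one row per
#'   label and `n_<stratum>` / `pct_<stratum>` columns, ordered by
#'   decreasing total count; stratum totals kept in attribute `totals`.
#' @export
concern_table <- function(counts, related_terms = NULL) {
  stopifnot(all(c("label", "stratum", "n") %in% names(counts)))
  counts <- counts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(pct = pct1(.data$n, sum(.data$n))) |>
    dplyr::ungroup()
  strata <- unique(counts$stratum)
  strata <- c(intersect("total", strata), setdiff(strata, "total"))
  totals <- counts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
    dplyr::arrange(match(.data$stratum, strata))
  wide <- counts |>
    dplyr::mutate(stratum = factor(.data$stratum, levels = strata)) |>
    tidyr::pivot_wider(
      names_from = "stratum", values_from = c("n", "pct"),
      names_vary = "slowest", values_fill = list(n = 0L)
    )
  ord_col <- if ("n_total" %in% names(wide)) "n_total" else names(wide)[[2]]
  wide <- wide[order(-wide[[ord_col]], wide$label), ]
  if (!is.null(related_terms)) {
    wide$related_terms <- unname(related_terms[wide$label])
  }
  structure(
    wide,
    class = c("concern_table", class(wide)),
    totals = setNames(totals$n, totals$stratum)
  )
}

#' Build the area-of-concern table from assignments
#'
#' Counts cluster memberships per labeled cluster, overall and per survey
#' stratum, and tabulates percentages with [concern_table()]. Clusters
#' without a label (not in `labels`, or labeled `NA`) are the "no
#' discernable semantic meaning" clusters: they are dropped from the table
#' before totals, though their responses still count in demographic
#' analyses. Percentages use the table's total assignment count as
#' denominator by default; per-response percentages (denominator = number
#' of meaningful responses) are available via `denominator`.
#'
#' @param assignments An [assign_responses()] result.
#' @param labels Named character vector (cluster id -> area label) or
#'   tibble (`cluster`, `label`); `NA` labels mark excluded clusters.
#' @param strata Tibble (`response_id`, `stratum`) or named vector; every
#'   assigned response must have a stratum, else an error names the
#'   offender.
#' @param related_terms Optional named annotation vector (label -> terms).
#' @param denominator `"assignments"` (default) or `"responses"`.
#' @return A [concern_table()].
#' @export
build_concern_table <- function(assignments, labels, strata,
                                related_terms = NULL,
                                denominator = c("assignments", "responses")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(labels)) {
    labels <- setNames(labels$label, as.character(labels$cluster))
  }
  if (is.data.frame(strata)) {
    strata <- setNames(strata$stratum, strata$response_id)
  }
  lab <- labels[as.character(assignments$cluster)]
  keep <- !is.na(lab)
  asg <- tibble(
    response_id = assignments$response_id[keep],
    label = unname(lab[keep])
  )
  asg$stratum <- unname(strata[asg$response_id])
  if (anyNA(asg$stratum)) {
    bad <- unique(asg$response_id[is.na(asg$stratum)])
    stop_invalid(paste0(
      "no stratum for response(s): ", paste(head(bad, 5), collapse = ", ")
    ))
  }
  long <- dplyr::bind_rows(
    dplyr::count(asg, .data$label, name = "n") |>
      dplyr::mutate(stratum = "total"),
    dplyr::count(asg, .data$label, .data$stratum, name = "n")
  )
  tab <- concern_table(
    long[, c("label", "stratum", "n")],
    related_terms = related_terms
  )
  if (denominator == "responses") {
    n_resp <- attr(assignments, "n_responses")
    pct_cols <- grep("^pct_", names(tab), value = TRUE)
    n_cols <- sub("^pct_", "n_", pct_cols)
    for (i in seq_along(pct_cols)) {
      tab[[pct_cols[i]]] <- pct1(tab[[n_cols[i]]], n_resp)
    }
  }
  tab
}

#' Concern-table bar chart
#'
#' @param object A [concern_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.concern_table <- function(object, ...) {
  pct_col <- if ("pct_total" %in% names(object)) "pct_total" else {
    grep("^pct_", names(object), value = TRUE)[[1]]
  }
  df <- tibble(label = object$label, pct = object[[pct_col]])
  ggplot(df, aes(x = stats::reorder(.data$label, .data$pct), y = .data$pct)) +
    geom_col() +
    coord_flip() +
    labs(
      x = NULL, y = "% of assignments",
      title = "Most frequently expressed areas of concern"
    ) +
    theme_minimal()
}
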