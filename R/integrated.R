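# The three-stage cascade (homology gate -> direct-partner voting ->
# shortest-distance transfer) and the real-weighted-combination (RWC)
# comparison method that fuses the three raw scores into one scalar.

#' Predict membrane types by the integrated three-stage cascade
#'
#' Exactly one stage fires for each query:
#' 1. If a training homolog passes the E-value gate, only the homology
#'    method is applied.
#' 2. Otherwise, if the query has at least one interactive training
#'    partner (confidence > 0), the network-based vote is applied.
#' 3. Otherwise the shortest-distance method decides (it never abstains).
#'
#' A sequence-less query skips the homology stage. The returned label set
#' is never empty.
#'
#' @param training Labelled protein table.
#' @param query One-row protein table (needs `id`; `sequence` optional).
#' @param interactions Interaction table.
#' @param hits Optional precomputed alignment hits (see
#'   [homology_hits()]); computed with the built-in aligner when `NULL`
#'   and the query has a sequence.
#' @param graph Optional precomputed weighted graph (built from
#'   `interactions` when `NULL`).
#' @param evalue_cutoff Homology gate (default 0.01).
#' @param t Top-t for the network stage (default [top_t()] of training).
#' @param transform Distance transform for [build_weighted_graph()].
#' @return A one-row prediction tibble whose `stage` records which method
#'   fired.
#' @export
predict_integrated <- function(training, query, interactions, hits = NULL,
                               graph = NULL, evalue_cutoff = 0.01,
                               t = NULL, transform = "linear") {
  qid <- query$id[[1]]
  qseq <- if ("sequence" %in% names(query)) query$sequence[[1]] else NA
  has_seq <- !is.null(qseq) && !is.na(qseq) && nzchar(qseq)
  if (has_seq || !is.null(hits)) {
    h <- predict_by_homology(training, query, hits = hits,
                             evalue_cutoff = evalue_cutoff)
    if (h$annotated) {
      return(h)
    }
  }
  n <- predict_by_network(training, qid, interactions, t = t)
  if (n$annotated) {
    return(n)
  }
  if (is.null(graph)) {
    graph <- build_weighted_graph(interactions, transform = transform)
  }
  predict_by_shortest_distance(training, qid, graph,
                               interactions = interactions)
}

#' Real-weighted-combination scores of a query against training candidates
#'
#' For each training candidate the alignment bit score, the direct
#' interaction confidence and the shortest distance are min-max normalized
#' to \[0, 1\] over the candidate set (the shortest distance inverted, so 1
#' is closest), then combined as
#' `S = alpha * s_hat + beta * w_hat + gamma * (1 - d_hat)`.
#' A component missing for a candidate (no alignment, no edge,
#' unreachable) contributes its worst normalized value 0; when all defined
#' values of a component coincide they all normalize to 1. It is an error
#' for every component of every candidate to be undefined.
#'
#' @inheritParams predict_integrated
#' @param weights Non-negative `c(alpha, beta, gamma)`, default
#'   `c(1, 1, 1) / 3`.
#' @return A tibble with one row per candidate: `candidate`, the raw and
#'   normalized components, and the combined `rwc`.
#' @export
rwc_scores <- function(training, query, interactions, hits = NULL,
                       graph = NULL, weights = c(1, 1, 1) / 3,
                       transform = "linear") {
  validate_proteins(training, require_labels = TRUE)
  if (length(weights) != 3 || any(weights < 0)) {
    stop("weights must be three non-negative numbers", call. = FALSE)
  }
  qid <- query$id[[1]]
  cand <- setdiff(training$id, qid)
  if (length(cand) == 0) {
    stop("no training candidates", call. = FALSE)
  }
  qseq <- if ("sequence" %in% names(query)) query$sequence[[1]] else NA
  if (is.null(hits) && !is.na(qseq) && nzchar(qseq)) {
    hits <- homology_hits(training[training$id %in% cand, , drop = FALSE],
                          queries = tibble::tibble(id = qid,
                                                   sequence = qseq))
  }
  s_raw <- rep(NA_real_, length(cand))
  if (!is.null(hits)) {
    h <- hits[hits$query_id == qid & hits$subject_id %in% cand, ,
              drop = FALSE]
    m <- match(cand, h$subject_id)
    s_raw[!is.na(m)] <- h$bitscore[m[!is.na(m)]]
  }
  w_direct <- interaction_weights(interactions, qid, cand)
  w_raw <- ifelse(w_direct > 0, w_direct, NA_real_)
  if (is.null(graph)) {
    graph <- build_weighted_graph(interactions, transform = transform)
  }
  d_raw <- rep(NA_real_, length(cand))
  if (igraph::gorder(graph) > 0 && qid %in% igraph::V(graph)$name) {
    sd_tbl <- shortest_distance(graph, qid)
    m <- match(cand, sd_tbl$id)
    d_raw[!is.na(m)] <- sd_tbl$distance[m[!is.na(m)]]
    d_raw[is.infinite(d_raw)] <- NA_real_
  }
  if (all(is.na(s_raw)) && all(is.na(w_raw)) && all(is.na(d_raw))) {
    stop("all RWC components undefined for every candidate", call. = FALSE)
  }
  s_hat <- minmax_unit(s_raw, constant = 1)
  w_hat <- minmax_unit(w_raw, constant = 1)
  d_hat_inv <- 1 - minmax_unit(d_raw, constant = 0)
  d_hat_inv[is.na(d_raw)] <- 0
  tibble::tibble(
    candidate = cand,
    bitscore = s_raw, confidence = w_raw, shortest_distance = d_raw,
    s_hat = s_hat, w_hat = w_hat, d_hat_inv = d_hat_inv,
    rwc = weights[1] * s_hat + weights[2] * w_hat +
      weights[3] * d_hat_inv
  )
}

# Min-max to [0, 1]; NA (missing) maps to 0. When all defined values
# coincide they carry no ranking information and map to `constant`
# (1 for higher-is-better components, 0 for distances so that the
# inverted value 1 - d_hat is 1, the best).
minmax_unit <- function(x, constant) {
  out <- numeric(length(x))
  ok <- !is.na(x)
  if (!any(ok)) {
    return(out)
  }
  rng <- range(x[ok])
  if (rng[1] == rng[2]) {
    out[ok] <- constant
  } else {
    out[ok] <- (x[ok] - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Predict types by the real-weighted-combination baseline
#'
#' Copies the label set of the training protein with the highest combined
#' RWC score (ties broken by lexicographic id).
#'
#' @inheritParams rwc_scores
#' @return A one-row prediction tibble with `stage = "rwc"`.
#' @export
predict_by_rwc <- function(training, query, interactions, hits = NULL,
                           graph = NULL, weights = c(1, 1, 1) / 3,
                           transform = "linear") {
  sc <- rwc_scores(training, query, interactions, hits = hits,
                   graph = graph, weights = weights, transform = transform)
  best <- sc[order(-sc$rwc, sc$candidate), ][1, ]
  labels <- training$types[[match(best$candidate, training$id)]]
  prediction_row(query$id[[1]], labels, "rwc",
                 detail = sprintf("best=%s rwc=%.3f", best$candidate,
                                  best$rwc))
}
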