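# Multi-label metrics, the leave-one-out harness with per-stage
# bookkeeping, the completely/partly/incorrectly-correct breakdown by
# type multiplicity, and the E-value sweep for the homology gate.

# Per-record scores. `actual`/`predicted` are integer type-index vectors.
record_precision <- function(actual, predicted) {
  length(intersect(actual, predicted)) / length(predicted)
}
record_recall <- function(actual, predicted) {
  length(intersect(actual, predicted)) / length(actual)
}
record_accuracy <- function(actual, predicted,
                            variant = c("recall_penalty", "jaccard")) {
  variant <- match.arg(variant)
  inter <- length(intersect(actual, predicted))
  if (variant == "recall_penalty") {
    inter / length(actual) -
      length(setdiff(predicted, actual)) / length(predicted)
  } else {
    inter / length(union(actual, predicted))
  }
}

annotated_records <- function(records) {
  stopifnot(all(c("actual", "predicted") %in% names(records)))
  records[records$annotated %||% rep(TRUE, nrow(records)), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-label Precision and Recall
#'
#' `Precision = (1/n) * sum |L ∩ L*| / |L*|` and
#' `Recall = (1/n) * sum |L ∩ L*| / |L|` over prediction records, where
#' `L` is the actual and `L*` the predicted label set. Abstentions
#' (`annotated = FALSE`) are excluded and must be accounted separately
#' (they are the NU column of an evaluation report). Neither metric is
#' sufficient alone: predicting every type forces Recall to 1, and
#' predicting any non-empty subset of the truth forces Precision to 1.
#'
#' @param records Tibble with list-columns `actual` and `predicted`
#'   (integer type indices) and optionally `annotated`.
#' @return One-row tibble with `n`, `precision`, `recall`.
#' @export
precision_recall <- function(records) {
  records <- annotated_records(records)
  if (nrow(records) == 0) {
    stop("no annotated prediction records", call. = FALSE)
  }
  tibble::tibble(
    n = nrow(records),
    precision = mean(purrr::map2_dbl(records$actual, records$predicted,
                                     record_precision)),
    recall = mean(purrr::map2_dbl(records$actual, records$predicted,
                                  record_recall))
  )
}

#' Multi-label Accuracy with an over-prediction penalty
#'
#' The default variant is the recall-minus-penalty form
#' `Acc = (1/n) * sum( |L ∩ L*|/|L| - |L* \\ L|/|L*| )`: the first term is
#' approximately the Recall and the second penalizes incorrectly predicted
#' types, vanishing when the prediction is exact. A per-record score is 1
#' iff the prediction equals the truth and -1 when the sets are disjoint.
#' The `"jaccard"` variant `(1/n) * sum |L ∩ L*| / |L ∪ L*|` lies in
#' \[0, 1\] and also equals 1 exactly at perfect predictions; both are
#' reported side by side in evaluation objects.
#'
#' @inheritParams precision_recall
#' @param variant `"recall_penalty"` (default) or `"jaccard"`.
#' @return A single real.
#' @export
multilabel_accuracy <- function(records,
                                variant = c("recall_penalty", "jaccard")) {
  variant <- match.arg(variant)
  records <- annotated_records(records)
  if (nrow(records) == 0) {
    stop("no annotated prediction records", call. = FALSE)
  }
  mean(purrr::map2_dbl(records$actual, records$predicted, record_accuracy,
                       variant = variant))
}

#' Completely / partly / incorrectly correct counts by type multiplicity
#'
#' Groups annotated records by the number of actual types and counts, per
#' group: `c` (predicted set equals the actual set), `p` (sets overlap but
#' differ) and `e` (sets are disjoint). `c + p + e` equals the group size.
#'
#' @inheritParams precision_recall
#' @return Tibble with columns `n_types`, `c`, `p`, `e`, `n`.
#' @export
breakdown_by_type_count <- function(records) {
  records <- annotated_records(records)
  cls <- purrr::map2_chr(records$actual, records$predicted, function(a, p) {
    if (setequal(a, p)) "c" else if (length(intersect(a, p)) > 0) "p"
    else "e"
  })
  out <- tibble::tibble(n_types = lengths(records$actual), class = cls)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$n_types),
    c = sum(.data$class == "c"),
    p = sum(.data$class == "p"),
    e = sum(.data$class == "e"),
    n = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$n_types)
}

#' Leave-one-out evaluation of a prediction method
#'
#' For each protein in turn its labels are hidden and its types are
#' predicted from the remaining labelled proteins. The interaction network
#' keeps the query's node and edges (only type knowledge is removed) and
#' the homology provider never returns self-hits. Expensive shared inputs
#' (all-against-all alignment hits, the weighted graph, PseAAC encodings)
#' are computed once up front.
#'
#' @param proteins Fully labelled protein table.
#' @param interactions Interaction table (may be empty / `NULL` for
#'   sequence-only methods).
#' @param method One of `"integrated"`, `"homology"`, `"network"`,
#'   `"shortest"`, `"nna"`, `"rwc"`.
#' @param evalue_cutoff Homology gate (default 0.01).
#' @param t Top-t for network voting (default [top_t()] of the dataset).
#' @param lambda,w PseAAC parameters for `"nna"`.
#' @param rwc_weights Component weights for `"rwc"`.
#' @param transform Distance transform for the weighted graph.
#' @param hits Optional precomputed all-against-all hit table (e.g. from
#'   [parse_blast_tabular()] on an external BLAST run); computed with the
#'   built-in aligner when needed.
#' @return An object of class `memtype_eval`: prediction records plus
#'   aggregate metrics, per-stage contributions and the c/p/e breakdown.
#'   Use [tidy()] for the records and [glance()] for the one-row summary.
#' @export
loo_evaluate <- function(proteins, interactions = NULL,
                         method = c("integrated", "homology", "network",
                                    "shortest", "nna", "rwc"),
                         evalue_cutoff = 0.01, t = NULL, lambda = 50,
                         w = 0.15, rwc_weights = c(1, 1, 1) / 3,
                         transform = "linear", hits = NULL) {
  method <- match.arg(method)
  validate_proteins(proteins, require_labels = TRUE)
  n <- nrow(proteins)
  if (is.null(interactions)) {
    interactions <- tibble::tibble(a = character(0), b = character(0),
                                   score = numeric(0))
  }
  needs_hits <- method %in% c("integrated", "homology", "rwc")
  if (needs_hits && is.null(hits)) {
    hits <- homology_hits(proteins)
  }
  needs_graph <- method %in% c("integrated", "shortest", "rwc")
  graph <- if (needs_graph) {
    build_weighted_graph(interactions, transform = transform)
  }
  encodings <- if (method == "nna") {
    encode_pseaac_dataset(proteins, lambda = lambda, w = w)
  }
  if (is.null(t) && method %in% c("integrated", "network")) {
    t <- top_t(proteins)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    training <- proteins[-i, , drop = FALSE]
    query <- proteins[i, , drop = FALSE]
    pred <- switch(method,
      integrated = predict_integrated(training, query, interactions,
                                      hits = hits, graph = graph,
                                      evalue_cutoff = evalue_cutoff,
                                      t = t),
      homology = predict_by_homology(training, query, hits = hits,
                                     evalue_cutoff = evalue_cutoff),
      network = predict_by_network(training, query$id, interactions,
                                   t = t),
      shortest = predict_by_shortest_distance(training, query$id, graph,
                                              interactions = interactions),
      nna = predict_by_nna(training, query, encodings = encodings,
                           lambda = lambda, w = w),
      rwc = predict_by_rwc(training, query, interactions, hits = hits,
                           graph = graph, weights = rwc_weights)
    )
    pred$actual <- list(proteins$types[[i]])
    rows[[i]] <- pred
  }
  records <- dplyr::bind_rows(rows)
  records <- dplyr::rename(records, predicted = "types")
  records <- records[, c("id", "actual", "predicted", "stage", "annotated",
                         "fallback", "detail")]
  new_memtype_eval(records, method,
                   config = list(evalue_cutoff = evalue_cutoff, t = t,
                                 lambda = lambda, w = w,
                                 rwc_weights = rwc_weights,
                                 transform = transform))
}

new_memtype_eval <- function(records, method, config = list()) {
  ann <- records[records$annotated, , drop = FALSE]
  stage_summary <- if (nrow(ann) > 0) {
    dplyr::summarise(
      dplyr::group_by(ann, .data$stage),
      n_annotated = dplyr::n(),
      acc = mean(purrr::map2_dbl(.data$actual, .data$predicted,
                                 record_accuracy)),
      acc_jaccard = mean(purrr::map2_dbl(.data$actual, .data$predicted,
                                         record_accuracy,
                                         variant = "jaccard")),
      .groups = "drop"
    )
  } else {
    tibble::tibble(stage = character(0), n_annotated = integer(0),
                   acc = numeric(0), acc_jaccard = numeric(0))
  }
  structure(
    list(records = records, method = method, stage_summary = stage_summary,
         n = nrow(records), n_annotated = nrow(ann),
         n_unannotated = nrow(records) - nrow(ann), config = config),
    class = "memtype_eval"
  )
}

#' @export
print.memtype_eval <- function(x, ...) {
  cat("Leave-one-out evaluation --", x$method, "method\n")
  cat(sprintf("  proteins: %d  annotated: %d  unannotated (NU): %d\n",
              x$n, x$n_annotated, x$n_unannotated))
  if (x$n_annotated > 0) {
    g <- glance(x)
    cat(sprintf("  Acc %.4f (jaccard %.4f)  Precision %.4f  Recall %.4f\n",
                g$acc, g$acc_jaccard, g$precision, g$recall))
    if (nrow(x$stage_summary) > 1) {
      cat("  per-stage contributions:\n")
      print(as.data.frame(x$stage_summary), row.names = FALSE)
    }
  }
  invisible(x)
}

#' Tidy the per-protein records of an evaluation
#'
#' @param x A `memtype_eval` object.
#' @param ... Unused.
#' @return The prediction records tibble (one row per protein: `id`,
#'   `actual`, `predicted`, `stage`, `annotated`, `fallback`).
#' @export
tidy.memtype_eval <- function(x, ...) {
  x$records
}

#' One-row summary of an evaluation
#'
#' @param x A `memtype_eval` object.
#' @param ... Unused.
#' @return One-row tibble: `method`, `n`, `n_annotated` (NA),
#'   `n_unannotated` (NU), `acc` (recall-minus-penalty variant),
#'   `acc_jaccard`, `precision`, `recall`.
#' @export
glance.memtype_eval <- function(x, ...) {
  if (x$n_annotated > 0) {
    pr <- precision_recall(x$records)
    acc <- multilabel_accuracy(x$records)
    accj <- multilabel_accuracy(x$records, variant = "jaccard")
  } else {
    pr <- tibble::tibble(precision = NA_real_, recall = NA_real_)
    acc <- NA_real_
    accj <- NA_real_
  }
  tibble::tibble(
    method = x$method, n = x$n, n_annotated = x$n_annotated,
    n_unannotated = x$n_unannotated, acc = acc, acc_jaccard = accj,
    precision = pr$precision, recall = pr$recall
  )
}

#' Homology-gate E-value sweep
#'
#' Repeats the leave-one-out homology-only evaluation at each cutoff.
#' Loosening the cutoff can only admit more hits, so the number of
#' unannotated proteins (NU) is non-increasing in the cutoff, while
#' admitting weak hits tends to lower Acc -- the trade-off that motivates
#' the 0.01 gate.
#'
#' @param proteins Fully labelled protein table.
#' @param cutoffs Numeric vector of at least two E-value cutoffs.
#' @param hits Optional precomputed hit table (computed once with the
#'   built-in aligner when `NULL`).
#' @return Tibble with one row per cutoff: `cutoff`, `n`, `n_annotated`,
#'   `n_unannotated`, `acc`, `acc_jaccard`, `precision`, `recall` (metric
#'   columns are `NA` when nothing is annotated).
#' @export
evalue_sweep <- function(proteins, cutoffs, hits = NULL) {
  if (length(cutoffs) < 2) {
    stop("need at least two cutoffs", call. = FALSE)
  }
  if (is.null(hits)) {
    hits <- homology_hits(proteins)
  }
  purrr::map_dfr(sort(cutoffs), function(ct) {
    ev <- loo_evaluate(proteins, method = "homology", evalue_cutoff = ct,
                       hits = hits)
    dplyr::bind_cols(tibble::tibble(cutoff = ct),
                     glance(ev)[, c("n", "n_annotated", "n_unannotated",
                                    "acc", "acc_jaccard", "precision",
                                    "recall")])
  })
}
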