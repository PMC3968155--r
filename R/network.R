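# Guilt-by-association over direct interaction partners: confidence-
# weighted voting over the six types with top-t multi-label selection.

#' Confidence scores between a query and each training protein
#'
#' @param training Labelled protein table.
#' @param query_id Query protein id (excluded from the result if present in
#'   `training`).
#' @param interactions Interaction table (`a`, `b`, `score`).
#' @return Named numeric vector over the training ids (0 where no
#'   interaction is recorded).
#' @export
interaction_scores <- function(training, query_id, interactions) {
  ids <- setdiff(training$id, query_id)
  interaction_weights(interactions, query_id, ids)
}

#' Confidence-weighted type probabilities
#'
#' For type k the probability is the confidence-weighted fraction of
#' training partners carrying type k:
#' `p_k = sum_q(w_q * l_qk) / sum_q(w_q)`. When the query has no
#' interactive training partner (all weights 0) every `p_k` is zero and
#' the network method must pass the query on.
#'
#' @param weights Non-negative numeric vector of confidence scores, one
#'   per training protein.
#' @param label_sets List of type-index vectors aligned with `weights`.
#' @param normalizer `"sum"` (default; divide by the total weight) or
#'   `"none"` (report the raw weighted type mass) for sensitivity checks.
#' @return A tibble with columns `index`, `name`, `probability`, plus an
#'   attribute `support` holding the total confidence mass used.
#' @examples
#' type_probabilities(c(2, 1), list(3L, 4L))
#' @export
type_probabilities <- function(weights, label_sets,
                               normalizer = c("sum", "none")) {
  normalizer <- match.arg(normalizer)
  if (length(weights) != length(label_sets)) {
    stop("weights and label sets must align", call. = FALSE)
  }
  if (any(weights < 0)) {
    stop("negative interaction weight", call. = FALSE)
  }
  mass <- numeric(6)
  for (q in seq_along(weights)) {
    if (weights[q] > 0 && length(label_sets[[q]]) > 0) {
      mass[label_sets[[q]]] <- mass[label_sets[[q]]] + weights[q]
    }
  }
  support <- sum(weights)
  p <- if (support > 0 && normalizer == "sum") mass / support else
    if (support > 0) mass else numeric(6)
  out <- tibble::tibble(index = 1:6, name = MEMBRANE_TYPE_NAMES,
                        probability = p)
  attr(out, "support") <- support
  out
}

#' Predict types by confidence-weighted voting over interaction partners
#'
#' Computes the type probabilities of the query from its direct training
#' partners and takes the `t` highest-probability types as the prediction,
#' where `t` defaults to the dataset's top-t (the ceiling of the mean
#' number of types per protein; 2 on the study's datasets). Only types with
#' positive probability are ever selected, so fewer than `t` types are
#' returned when fewer are supported; ties at the t-th rank are broken by
#' smaller type index. With no interactive training partner the method
#' abstains.
#'
#' @inheritParams interaction_scores
#' @param t Number of top types to select (default [top_t()] of the
#'   training set); must be in 1..6.
#' @param normalizer Passed to [type_probabilities()].
#' @return A one-row prediction tibble (see [predict_by_homology()]).
#' @export
predict_by_network <- function(training, query_id, interactions, t = NULL,
                               normalizer = "sum") {
  validate_proteins(training, require_labels = TRUE)
  if (is.null(t)) {
    t <- top_t(training)
  }
  if (t < 1 || t > 6) {
    stop("t must be between 1 and 6", call. = FALSE)
  }
  w <- interaction_scores(training, query_id, interactions)
  keep <- match(names(w), training$id)
  probs <- type_probabilities(w, training$types[keep],
                              normalizer = normalizer)
  p <- probs$probability
  if (all(p == 0)) {
    return(prediction_row(query_id, integer(0), "network",
                          annotated = FALSE))
  }
  ord <- order(-p, seq_along(p))
  sel <- ord[seq_len(t)]
  sel <- sort(sel[p[sel] > 0])
  prediction_row(query_id, sel, "network",
                 detail = sprintf("support=%.0f p=[%s]",
                                  attr(probs, "support"),
                                  paste(signif(p, 3), collapse = ",")))
}
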