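# Small hand-built fixtures shared across test files.

# A labelled protein table from parallel vectors; types given as lists
# of indices.
make_proteins <- function(ids, types, sequences = NULL) {
  tibble::tibble(
    id = ids,
    sequence = sequences %||% rep(NA_character_, length(ids)),
    types = lapply(types, as.integer)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_interactions <- function(a, b, score) {
  tibble::tibble(a = a, b = b, score = as.numeric(score))
}

# Prediction records for metric tests.
make_records <- function(actual, predicted, annotated = NULL) {
  tibble::tibble(
    id = sprintf("r%d", seq_along(actual)),
    actual = lapply(actual, as.integer),
    predicted = lapply(predicted, as.integer),
    annotated = annotated %||% rep(TRUE, length(actual))
  )
}
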