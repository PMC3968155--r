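# Six-class membrane protein taxonomy and the 0/1 label encoding.
# The index order is fixed; every label vector, probability vector and
# report in the package uses it.

MEMBRANE_TYPE_NAMES <- c(
  "GPI-anchor",
  "lipid-anchor",
  "multi-pass",
  "peripheral",
  "single-pass type I",
  "single-pass type II"
)

#' The six membrane protein types
#'
#' Membrane proteins are classified by their intramolecular arrangement and
#' position in the cell into six types. The 1-based index order returned
#' here is fixed and is used by every label vector in the package.
#'
#' @return A tibble with columns `index` (integer, 1..6) and `name`
#'   (character).
#' @examples
#' membrane_types()
#' @export
membrane_types <- function() {
  tibble::tibble(index = 1:6, name = MEMBRANE_TYPE_NAMES)
}

#' Resolve membrane type names or indices to indices
#'
#' Accepts type names (exact, case-insensitive) or 1-based indices (numeric,
#' or strings of digits) and returns sorted unique integer indices.
#'
#' @param x Character or numeric vector of type names and/or indices.
#' @return Sorted integer vector of type indices in 1..6.
#' @examples
#' as_type_index(c("multi-pass", "1"))
#' as_type_index(c(5, 5, 2))
#' @export
as_type_index <- function(x) {
  if (length(x) == 0) {
    return(integer(0))
  }
  if (is.numeric(x)) {
    idx <- as.integer(x)
    if (any(is.na(idx) | idx != x | idx < 1 | idx > 6)) {
      bad <- x[is.na(idx) | idx != x | idx < 1 | idx > 6]
      stop("unknown membrane type index: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(sort(unique(idx)))
  }
  x <- trimws(as.character(x))
  idx <- match(tolower(x), tolower(MEMBRANE_TYPE_NAMES))
  numeric_like <- grepl("^[0-9]+$", x)
  idx[numeric_like] <- suppressWarnings(as.integer(x[numeric_like]))
  bad <- is.na(idx) | idx < 1 | idx > 6
  if (any(bad)) {
    stop("unknown membrane type: ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  sort(unique(as.integer(idx)))
}

#' Encode a set of membrane types as a 6-component 0/1 label vector
#'
#' Component k is 1 exactly when the protein carries type k. Training
#' proteins must carry at least one type, so the empty set is rejected.
#'
#' @param types Membrane types as indices or names (see [as_type_index()]).
#' @return Named integer vector of length 6 with values in \{0, 1\}.
#' @examples
#' encode_labels("multi-pass")
#' encode_labels(c(1, 2))
#' @seealso [decode_labels()]
#' @export
encode_labels <- function(types) {
  idx <- as_type_index(types)
  if (length(idx) == 0) {
    stop("label set must be non-empty", call. = FALSE)
  }
  v <- integer(6)
  v[idx] <- 1L
  names(v) <- MEMBRANE_TYPE_NAMES
  v
}

#' Decode a 0/1 label vector back to type indices
#'
#' @param label_vector Numeric vector of length 6 over \{0, 1\}.
#' @return Sorted integer vector of the type indices with component 1.
#' @examples
#' decode_labels(encode_labels(c("GPI-anchor", "peripheral")))
#' @export
decode_labels <- function(label_vector) {
  if (length(label_vector) != 6 || !all(label_vector %in% c(0, 1))) {
    stop("label vector must have 6 components over {0, 1}", call. = FALSE)
  }
  unname(which(label_vector == 1))
}

#' Names of a set of type indices
#'
#' @param idx Integer vector of type indices in 1..6.
#' @return Character vector of type names.
#' @export
type_names <- function(idx) {
  MEMBRANE_TYPE_NAMES[as_type_index(idx)]
}

# Validate a protein table: tibble with `id` (chr, unique), `sequence`
# (chr, may be NA/empty), `types` (list of integer index vectors).
validate_proteins <- function(proteins, require_labels = FALSE) {
  stopifnot(is.data.frame(proteins))
  if (!all(c("id", "types") %in% names(proteins))) {
    stop("protein table needs columns `id` and `types`", call. = FALSE)
  }
  if (anyDuplicated(proteins$id)) {
    stop("duplicate protein ids: ",
         paste(unique(proteins$id[duplicated(proteins$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (require_labels) {
    n_lab <- lengths(proteins$types)
    if (any(n_lab == 0)) {
      stop("all training proteins must be labelled; unlabelled: ",
           paste(utils::head(proteins$id[n_lab == 0], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(proteins)
}

#' Mean number of types per protein and the top-t rule
#'
#' `average_type_count()` is the mean label-set size over a labelled protein
#' table. `top_t()` is the smallest integer greater than or equal to that
#' mean; it is the number of types the network-based method selects. On the
#' study's three human datasets the means were 1.028, 1.035 and 1.037, so
#' top-t is 2 throughout.
#'
#' @param proteins Protein table with an `id` and a `types` list-column of
#'   type indices; every protein must be labelled.
#' @return `average_type_count()`: a single real; `top_t()`: a single
#'   integer.
#' @examples
#' prot <- tibble::tibble(
#'   id = c("a", "b", "c"),
#'   types = list(1L, c(2L, 3L), c(1L, 4L, 6L))
#' )
#' average_type_count(prot)
#' top_t(prot)
#' @export
average_type_count <- function(proteins) {
  validate_proteins(proteins, require_labels = TRUE)
  if (nrow(proteins) == 0) {
    stop("empty dataset", call. = FALSE)
  }
  mean(lengths(proteins$types))
}

#' @rdname average_type_count
#' @export
top_t <- function(proteins) {
  as.integer(ceiling(average_type_count(proteins)))
}

#' Summarise a labelled protein dataset
#'
#' Reports the counts underlying a dataset description: number of proteins,
#' mean types per protein, the derived top-t, and the per-multiplicity
#' histogram.
#'
#' @inheritParams average_type_count
#' @return A one-row tibble with columns `n_proteins`, `mean_types`,
#'   `top_t`, and `n_with_1`..`n_with_3` multiplicity counts (observed
#'   data never exceed 3 types; higher multiplicities are counted in
#'   `n_with_more`).
#' @export
summarise_dataset <- function(proteins) {
  validate_proteins(proteins, require_labels = TRUE)
  m <- lengths(proteins$types)
  tibble::tibble(
    n_proteins = nrow(proteins),
    mean_types = mean(m),
    top_t = as.integer(ceiling(mean(m))),
    n_with_1 = sum(m == 1),
    n_with_2 = sum(m == 2),
    n_with_3 = sum(m == 3),
    n_with_more = sum(m > 3)
  )
}
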