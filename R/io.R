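# Readers and writers for the three plain-text interchange formats:
# FASTA sequences, tab-delimited annotation tables, and 3-column
# STRING-style edge lists. All readers return tibbles.

NONSTANDARD_RESIDUES <- c("B", "Z", "X", "U", "O", "*")

#' Read protein sequences from a FASTA file
#'
#' The header token up to the first whitespace is taken as the protein id;
#' sequences are uppercased. Non-standard residues (B, Z, X, U, O, `*`) are
#' preserved in the sequence but flagged in the `has_nonstandard` column
#' (with a warning naming the ids).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `sequence`, `has_nonstandard` and an
#'   empty `types` list-column (labels unknown until annotated; see
#'   [add_annotations()]).
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  sequence <- toupper(as.character(seqs))
  nonstd <- stringr::str_detect(
    sequence,
    paste0("[", paste(sub("\\*", "\\\\*", NONSTANDARD_RESIDUES), collapse = ""), "]")
  )
  if (any(nonstd)) {
    warning("non-standard residues (B/Z/X/U/O/*) in: ",
            paste(ids[nonstd], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    id = unname(ids),
    sequence = unname(sequence),
    has_nonstandard = unname(nonstd),
    types = rep(list(integer(0)), length(ids))
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins Protein table with `id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  keep <- !is.na(proteins$sequence) & nzchar(proteins$sequence)
  lines <- rbind(paste0(">", proteins$id[keep]), proteins$sequence[keep])
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read a membrane-type annotation table
#'
#' One row per protein: an id, a delimiter, and one or more membrane types
#' given as names or 1-based indices separated by `type_sep`. A row with no
#' recognizable type is an error (reported with its row number), as is an
#' unknown type name.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter between the id and the type list (default
#'   tab).
#' @param type_sep Delimiter between multiple types (default `";"`).
#' @return A tibble with columns `id` and `types` (list of sorted integer
#'   type indices).
#' @examples
#' tf <- tempfile()
#' writeLines(c("Q9UMF0\tsingle-pass type I", "X1\t1;2"), tf)
#' read_annotations(tf)
#' @export
read_annotations <- function(path, delim = "\t", type_sep = ";") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop("empty annotation file: ", path, call. = FALSE)
  }
  parts <- stringr::str_split_fixed(lines, stringr::fixed(delim), 2)
  ids <- trimws(parts[, 1])
  types <- purrr::imap(parts[, 2], function(field, row) {
    toks <- trimws(strsplit(field, type_sep, fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) {
      stop("annotation row ", row, " has no recognizable types", call. = FALSE)
    }
    tryCatch(as_type_index(toks), error = function(e) {
      stop("annotation row ", row, ": ", conditionMessage(e), call. = FALSE)
    })
  })
  if (anyDuplicated(ids)) {
    stop("duplicate ids in annotation file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, types = types)
}

#' Write an annotation table
#'
#' @param proteins Labelled protein table.
#' @param path Output path.
#' @param delim,type_sep Delimiters, as in [read_annotations()].
#' @param use_names Write type names (default) rather than indices.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(proteins, path, delim = "\t", type_sep = ";",
                              use_names = TRUE) {
  validate_proteins(proteins, require_labels = TRUE)
  fields <- purrr::map_chr(proteins$types, function(t) {
    paste(if (use_names) MEMBRANE_TYPE_NAMES[t] else t, collapse = type_sep)
  })
  writeLines(paste(proteins$id, fields, sep = delim), path)
  invisible(path)
}

#' Attach annotations to a protein table
#'
#' Joins a `types` label column (e.g. from [read_annotations()]) onto a
#' sequence table (e.g. from [read_fasta()]) by id.
#'
#' @param proteins Protein table with an `id` column.
#' @param annotations Tibble with `id` and `types` columns.
#' @param require_all Error if any protein is left unannotated (default
#'   `TRUE`).
#' @return The protein table with its `types` list-column filled in.
#' @export
add_annotations <- function(proteins, annotations, require_all = TRUE) {
  m <- match(proteins$id, annotations$id)
  if (require_all && anyNA(m)) {
    stop("no annotation for: ",
         paste(utils::head(proteins$id[is.na(m)], 5), collapse = ", "),
         call. = FALSE)
  }
  proteins$types <- purrr::map(m, function(i) {
    if (is.na(i)) integer(0) else annotations$types[[i]]
  })
  proteins
}

#' Read a STRING-style interaction edge list
#'
#' Expects a whitespace- or tab-delimited file with three columns: idA, idB
#' and a combined confidence score. Scores are stored on the raw STRING
#' 0--1000 scale; with `scale = "unit"` scores in (0, 1] are multiplied by
#' 1000 on ingest, and with `scale = "auto"` the unit scale is assumed when
#' no score exceeds 1. Two proteins are regarded interactive only when
#' their confidence is greater than zero, so rows with score <= 0 are
#' dropped, as are self-edges. Duplicate (a,b)/(b,a) rows must agree, else
#' the maximum is kept with a warning.
#'
#' @param path Path to the edge list.
#' @param scale One of `"auto"`, `"raw1000"`, `"unit"`.
#' @param comment Lines starting with this prefix are skipped (default
#'   `"#"`); a `protein1 protein2 combined_score` header row is skipped too.
#' @return A tibble with columns `a`, `b`, `score`, one row per unordered
#'   pair with `a < b` lexicographically.
#' @export
read_interactions <- function(path, scale = c("auto", "raw1000", "unit"),
                              comment = "#") {
  scale <- match.arg(scale)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), comment)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) > 0 &&
      grepl("^\\s*protein1\\s", lines[1], ignore.case = TRUE)) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (length(lines) == 0) {
    return(tibble::tibble(a = character(0), b = character(0),
                          score = numeric(0)))
  }
  toks <- stringr::str_split(trimws(lines), "[ \t]+")
  n_tok <- lengths(toks)
  if (any(n_tok != 3)) {
    stop("malformed edge list row at line ", line_no[which(n_tok != 3)[1]],
         ": expected 3 columns", call. = FALSE)
  }
  m <- matrix(unlist(toks), ncol = 3, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    stop("non-numeric confidence score at line ", line_no[which(is.na(w))[1]],
         call. = FALSE)
  }
  if (scale == "auto") {
    scale <- if (all(w <= 1)) "unit" else "raw1000"
  }
  if (scale == "unit") {
    if (any(w > 1)) {
      stop("score > 1 under unit scale at line ", line_no[which(w > 1)[1]],
           call. = FALSE)
    }
    w <- w * 1000
  } else if (any(w > 1000)) {
    stop("score > 1000 under raw1000 scale at line ",
         line_no[which(w > 1000)[1]], call. = FALSE)
  }
  edges <- tibble::tibble(a = m[, 1], b = m[, 2], score = w)
  edges <- dplyr::filter(edges, .data$score > 0, .data$a != .data$b)
  if (nrow(edges) == 0) {
    return(edges)
  }
  # canonicalise unordered pairs, then reconcile duplicates
  swap <- edges$a > edges$b
  tmp <- edges$a[swap]
  edges$a[swap] <- edges$b[swap]
  edges$b[swap] <- tmp
  dup <- dplyr::group_by(edges, .data$a, .data$b)
  disagree <- dplyr::filter(
    dplyr::summarise(dup, spread = max(.data$score) - min(.data$score),
                     .groups = "drop"),
    .data$spread > 0
  )
  if (nrow(disagree) > 0) {
    warning("conflicting duplicate scores for ",
            paste(paste0(disagree$a, "-", disagree$b), collapse = ", "),
            "; keeping the maximum", call. = FALSE)
  }
  out <- dplyr::summarise(dup, score = max(.data$score), .groups = "drop")
  dplyr::arrange(out, .data$a, .data$b)
}

#' Write an interaction table as a 3-column edge list
#'
#' @param interactions Interaction table (`a`, `b`, `score`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  writeLines(
    paste(interactions$a, interactions$b,
          format(interactions$score, trim = TRUE, scientific = FALSE),
          sep = "\t"),
    path
  )
  invisible(path)
}

# Confidence scores between `query_id` and each of `ids` (0 when absent).
interaction_weights <- function(interactions, query_id, ids) {
  w <- stats::setNames(numeric(length(ids)), ids)
  if (is.null(interactions) || nrow(interactions) == 0) {
    return(w)
  }
  hit_a <- interactions$a == query_id
  hit_b <- interactions$b == query_id
  partners <- c(interactions$b[hit_a], interactions$a[hit_b])
  scores <- c(interactions$score[hit_a], interactions$score[hit_b])
  m <- match(ids, partners)
  w[!is.na(m)] <- scores[m[!is.na(m)]]
  w
}
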