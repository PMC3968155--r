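# Homology transfer: an alignment-hit provider layer (built-in local
# aligner or an external BLAST tabular report), the Karlin-Altschul
# E-value approximation, and best-hit label transfer behind the paper's
# E-value gate.

# Karlin-Altschul parameters for gapped BLOSUM62 with gap open 11 /
# extend 1, the standard values reported by BLAST for this scoring
# system. They gate only the E-value cutoff decision; label transfer
# itself depends on the score ordering.
KA_LAMBDA <- 0.267
KA_K <- 0.041

# Residues outside the BLOSUM62 alphabet are mapped to X for scoring.
sanitize_for_alignment <- function(seq) {
  chartr("UO*", "XXX", toupper(seq))
}

#' Smith-Waterman local alignment score with an approximate E-value
#'
#' Optimal local alignment under BLOSUM62 with affine gap costs (a gap of
#' length k costs `gap_open + k * gap_extend`, the BLAST 11/1 convention).
#' The E-value is the Karlin-Altschul approximation
#' `E = K * m * n * exp(-lambda * S)` with the fixed gapped-BLOSUM62
#' constants `lambda = 0.267`, `K = 0.041`, and `m`, `n` the two sequence
#' lengths. The bit score is `(lambda * S - log K) / log 2`.
#'
#' @param seq_a,seq_b Amino-acid sequences (non-empty strings).
#' @param gap_open,gap_extend Affine gap costs (defaults 11 and 1).
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @return A one-row tibble with `score` (raw), `bitscore`, `evalue`.
#' @examples
#' align_local("HEAGAWGHEE", "PAWHEAE")
#' @export
align_local <- function(seq_a, seq_b, gap_open = 11, gap_extend = 1,
                        substitution_matrix = "BLOSUM62") {
  if (!nzchar(seq_a) || !nzchar(seq_b) || is.na(seq_a) || is.na(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  s <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(sanitize_for_alignment(seq_a)),
    subject = Biostrings::AAString(sanitize_for_alignment(seq_b)),
    type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open,
    gapExtension = gap_extend,
    scoreOnly = TRUE
  )
  tibble::tibble(
    score = s,
    bitscore = (KA_LAMBDA * s - log(KA_K)) / log(2),
    evalue = karlin_altschul_evalue(s, nchar(seq_a), nchar(seq_b))
  )
}

karlin_altschul_evalue <- function(raw_score, m, n) {
  KA_K * as.numeric(m) * as.numeric(n) * exp(-KA_LAMBDA * raw_score)
}

#' All-against-all alignment hits with the built-in aligner
#'
#' Aligns every query against every subject (excluding self-hits, so the
#' table is safe for leave-one-out use) and returns one hit per ordered
#' pair. Scores are symmetric; each unordered pair is aligned once.
#'
#' @param proteins Protein table with `id` and `sequence`; rows without a
#'   sequence are skipped as queries and subjects.
#' @param queries Optional protein table of queries (default: `proteins`
#'   against itself).
#' @inheritParams align_local
#' @return A tibble of hits: `query_id`, `subject_id`, `score`, `bitscore`,
#'   `evalue`.
#' @export
homology_hits <- function(proteins, queries = NULL, gap_open = 11,
                          gap_extend = 1,
                          substitution_matrix = "BLOSUM62") {
  has_seq <- function(d) !is.na(d$sequence) & nzchar(d$sequence)
  subjects <- proteins[has_seq(proteins), , drop = FALSE]
  self <- is.null(queries)
  if (self) queries <- subjects else queries <- queries[has_seq(queries), ]
  if (nrow(subjects) == 0 || nrow(queries) == 0) {
    return(empty_hits())
  }
  subj_set <- Biostrings::AAStringSet(
    sanitize_for_alignment(subjects$sequence)
  )
  rows <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    # against itself the score matrix is symmetric: only align j > i
    take <- if (self) seq_len(nrow(subjects)) > i else
      subjects$id != queries$id[i]
    if (!any(take)) {
      rows[[i]] <- NULL
      next
    }
    s <- Biostrings::pairwiseAlignment(
      pattern = subj_set[take],
      subject = Biostrings::AAString(
        sanitize_for_alignment(queries$sequence[i])
      ),
      type = "local",
      substitutionMatrix = substitution_matrix,
      gapOpening = gap_open,
      gapExtension = gap_extend,
      scoreOnly = TRUE
    )
    rows[[i]] <- tibble::tibble(
      query_id = queries$id[i],
      subject_id = subjects$id[take],
      score = s,
      evalue = karlin_altschul_evalue(
        s, nchar(queries$sequence[i]), nchar(subjects$sequence[take])
      )
    )
  }
  hits <- dplyr::bind_rows(rows)
  hits$bitscore <- (KA_LAMBDA * hits$score - log(KA_K)) / log(2)
  if (self && nrow(hits) > 0) {
    mirror <- hits
    mirror$query_id <- hits$subject_id
    mirror$subject_id <- hits$query_id
    hits <- dplyr::bind_rows(hits, mirror)
  }
  dplyr::select(hits, "query_id", "subject_id", "score", "bitscore",
                "evalue")
}

empty_hits <- function() {
  tibble::tibble(query_id = character(0), subject_id = character(0),
                 score = numeric(0), bitscore = numeric(0),
                 evalue = numeric(0))
}

#' Parse a BLAST tabular (outfmt 6) report
#'
#' Reads the standard 12-column report (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore),
#' keeping query id, subject id, E-value and bit score. Self-hits are
#' discarded and multiple HSPs for the same pair are collapsed to the one
#' with the best bit score.
#'
#' @param path Path to the tabular report.
#' @param query_set,subject_set Optional character vectors of permissible
#'   ids; rows referring to other ids are an error.
#' @return A tibble of hits as in [homology_hits()] (with `score` set to
#'   the bit score).
#' @export
parse_blast_tabular <- function(path, query_set = NULL, subject_set = NULL) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  toks <- stringr::str_split(trimws(lines), "[ \t]+")
  if (any(lengths(toks) < 12)) {
    stop("line ", line_no[which(lengths(toks) < 12)[1]],
         ": expected 12 tab-separated columns", call. = FALSE)
  }
  m <- t(vapply(toks, function(x) x[1:12], character(12)))
  evalue <- suppressWarnings(as.numeric(m[, 11]))
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(evalue) || anyNA(bitscore)) {
    stop("line ", line_no[which(is.na(evalue) | is.na(bitscore))[1]],
         ": non-numeric evalue or bitscore", call. = FALSE)
  }
  hits <- tibble::tibble(query_id = m[, 1], subject_id = m[, 2],
                         evalue = evalue, bitscore = bitscore)
  if (!is.null(query_set) && any(!hits$query_id %in% query_set)) {
    stop("unknown query id: ",
         hits$query_id[!hits$query_id %in% query_set][1], call. = FALSE)
  }
  if (!is.null(subject_set) && any(!hits$subject_id %in% subject_set)) {
    stop("unknown subject id: ",
         hits$subject_id[!hits$subject_id %in% subject_set][1],
         call. = FALSE)
  }
  hits <- dplyr::filter(hits, .data$query_id != .data$subject_id)
  hits <- dplyr::slice_min(
    dplyr::group_by(hits, .data$query_id, .data$subject_id),
    order_by = tibble::tibble(-bitscore, evalue), n = 1, with_ties = FALSE
  )
  hits <- dplyr::ungroup(hits)
  hits$score <- hits$bitscore
  dplyr::select(hits, "query_id", "subject_id", "score", "bitscore",
                "evalue")
}

#' Transfer labels from the best homolog passing an E-value gate
#'
#' Among alignment hits of the query against the training set with
#' `evalue <= evalue_cutoff`, the subject with maximal bit score is chosen
#' (ties broken by smaller E-value, then lexicographic subject id) and its
#' full label set is copied to the query. When no hit passes the gate the
#' method abstains: the query has no homolog in the training set and a
#' downstream method must decide.
#'
#' @param training Labelled protein table.
#' @param query A one-row protein table (or a list with `id` and
#'   `sequence`). A sequence-less query is an error, distinct from
#'   abstention.
#' @param hits Optional precomputed hit table ([homology_hits()] or
#'   [parse_blast_tabular()]); when `NULL` the built-in aligner is run.
#' @param evalue_cutoff Homology gate (default 0.01).
#' @return A one-row prediction tibble: `id`, `types` (list-column; empty
#'   on abstention), `stage`, `annotated`, `fallback`, `detail`.
#' @export
predict_by_homology <- function(training, query, hits = NULL,
                                evalue_cutoff = 0.01) {
  validate_proteins(training, require_labels = TRUE)
  qid <- query$id[[1]]
  if (is.null(hits)) {
    qseq <- query$sequence[[1]]
    if (is.null(qseq) || is.na(qseq) || !nzchar(qseq)) {
      stop("query ", qid, " has no sequence; homology prediction needs one",
           call. = FALSE)
    }
    hits <- homology_hits(training,
                          queries = tibble::tibble(id = qid, sequence = qseq))
  }
  cand <- dplyr::filter(
    hits,
    .data$query_id == qid,
    .data$subject_id != qid,
    .data$subject_id %in% training$id,
    .data$evalue <= evalue_cutoff
  )
  if (nrow(cand) == 0) {
    return(prediction_row(qid, integer(0), "homology", annotated = FALSE))
  }
  best <- cand[order(-cand$bitscore, cand$evalue, cand$subject_id), ][1, ]
  labels <- training$types[[match(best$subject_id, training$id)]]
  prediction_row(qid, labels, "homology",
                 detail = sprintf("best_hit=%s evalue=%.3g bitscore=%.1f",
                                  best$subject_id, best$evalue,
                                  best$bitscore))
}

prediction_row <- function(id, types, stage, annotated = length(types) > 0,
                           fallback = FALSE, detail = NA_character_) {
  tibble::tibble(
    id = id,
    types = list(as.integer(types)),
    stage = stage,
    annotated = annotated,
    fallback = fallback,
    detail = detail
  )
}
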