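# Pseudo amino acid composition: 20 amino-acid frequencies plus, for
# each of five physicochemical/biochemical property profiles, lambda
# tiered sequence-order correlation factors -- 20 + 5*50 = 270 components
# with the default lambda = 50 -- and the nearest-neighbour baseline on
# top of the encoding.

AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PROPERTY_ORDER <- c("polarity", "secondary_structure", "molecular_volume",
                    "codon_diversity", "electrostatic_charge")

# Original (unstandardized) property values for the 20 amino acids:
# polarity, secondary-structure propensity, molecular volume, codon
# diversity and electrostatic charge.
AA_PROPERTY_VALUES <- matrix(c(
  # polarity, secondary, volume,  codon,  charge
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_ORDER, PROPERTY_ORDER))

#' Physicochemical and biochemical property values of the 20 amino acids
#'
#' Five property profiles (polarity, secondary-structure propensity,
#' molecular volume, codon diversity, electrostatic charge), either as the
#' original literature values or standardized per column to mean 0 and
#' unit standard deviation over the 20 amino acids.
#'
#' @param standardized Return the standardized values (default `FALSE`).
#' @return A tibble with column `aa` plus the five property columns, 20
#'   rows in alphabetical amino-acid order.
#' @export
aa_properties <- function(standardized = FALSE) {
  m <- AA_PROPERTY_VALUES
  if (standardized) {
    m <- apply(m, 2, standardize_property)
    rownames(m) <- AA_ORDER
  }
  dplyr::bind_cols(tibble::tibble(aa = AA_ORDER), tibble::as_tibble(m))
}

#' Standardize a 20-value property column
#'
#' Centres the 20 original amino-acid property values and scales them to
#' unit standard deviation: `F(a) = (F0(a) - mean(F0)) / sd(F0)`. Rank
#' order is preserved (the transform is affine and increasing).
#'
#' @param values Numeric vector of 20 finite property values.
#' @return Numeric vector with mean 0 and standard deviation 1.
#' @export
standardize_property <- function(values) {
  if (length(values) != 20 || !all(is.finite(values))) {
    stop("a property column has 20 finite values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("property column has zero variance", call. = FALSE)
  }
  (values - mean(values)) / s
}

# Indices (1..20) of the standard residues of `sequence`, dropping
# non-standard letters with a warning.
sequence_indices <- function(sequence, warn = TRUE) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, AA_ORDER)
  if (anyNA(idx) && warn) {
    warning("dropping non-standard residues: ",
            paste(unique(chars[is.na(idx)]), collapse = ", "),
            call. = FALSE)
  }
  idx[!is.na(idx)]
}

#' Tiered sequence-order correlation factors for one property
#'
#' For tier j = 1..lambda,
#' `theta_j = mean over i of (F(P[i+j]) - F(P[i]))^2`,
#' where `F` is the standardized property value of a residue. The sequence
#' must be longer than `lambda` (after dropping non-standard residues).
#'
#' @param sequence Amino-acid sequence.
#' @param values Property values for the 20 amino acids, named by residue
#'   (standardized internally unless `standardize = FALSE`).
#' @param lambda Number of tiers (default 50).
#' @param standardize Standardize `values` first (default `TRUE`).
#' @return Numeric vector `theta_1..theta_lambda`.
#' @export
correlation_factors <- function(sequence, values, lambda = 50,
                                standardize = TRUE) {
  if (standardize) {
    values <- stats::setNames(standardize_property(unname(values[AA_ORDER])),
                              AA_ORDER)
  }
  idx <- sequence_indices(sequence)
  L <- length(idx)
  if (L <= lambda) {
    stop("sequence too short for lambda = ", lambda, ": ", L,
         " standard residues in ", substr(sequence, 1, 20),
         if (nchar(sequence) > 20) "..." else "", call. = FALSE)
  }
  f <- unname(values[AA_ORDER])[idx]
  vapply(seq_len(lambda), function(j) {
    mean((f[(1 + j):L] - f[1:(L - j)])^2)
  }, numeric(1))
}

#' Encode a protein sequence as a pseudo amino acid composition vector
#'
#' The first 20 components are the relative amino-acid frequencies; the
#' remaining `5 * lambda` components are the correlation factors of the
#' five property profiles (in the order polarity, secondary structure,
#' molecular volume, codon diversity, electrostatic charge), each scaled
#' by the sequence-order weight `w`. The whole vector is normalized by
#' `D = sum(f) + w * sum(theta)` so its components sum to 1. With the
#' defaults (`lambda = 50`, five properties) the vector has
#' 20 + 50*5 = 270 components.
#'
#' @param sequence Amino-acid sequence with more than `lambda` standard
#'   residues (non-standard residues are dropped with a warning).
#' @param lambda Number of correlation tiers per property (default 50).
#' @param w Sequence-order weight (default 0.15).
#' @param properties Property table as returned by [aa_properties()]
#'   (original values; standardized internally).
#' @return Named numeric vector of length `20 + 5 * lambda` summing to 1.
#' @export
encode_pseaac <- function(sequence, lambda = 50, w = 0.15,
                          properties = aa_properties()) {
  idx <- sequence_indices(sequence)
  L <- length(idx)
  if (L <= lambda) {
    stop("sequence too short for lambda = ", lambda, ": ", L,
         " standard residues", call. = FALSE)
  }
  f <- tabulate(idx, nbins = 20) / L
  theta <- unlist(lapply(PROPERTY_ORDER, function(p) {
    vals <- stats::setNames(properties[[p]], properties$aa)
    suppressWarnings(
      correlation_factors(sequence, vals, lambda = lambda)
    )
  }))
  d <- sum(f) + w * sum(theta)
  x <- c(f, w * theta) / d
  names(x) <- c(AA_ORDER,
                paste0(rep(PROPERTY_ORDER, each = lambda), "_",
                       rep(seq_len(lambda), times = 5)))
  x
}

#' Encode every sequence of a protein table
#'
#' @param proteins Protein table with `id` and `sequence`.
#' @inheritParams encode_pseaac
#' @return A numeric matrix, one row per protein (rownames = ids).
#' @export
encode_pseaac_dataset <- function(proteins, lambda = 50, w = 0.15,
                                  properties = aa_properties()) {
  enc <- lapply(proteins$sequence, encode_pseaac, lambda = lambda, w = w,
                properties = properties)
  m <- do.call(rbind, enc)
  rownames(m) <- proteins$id
  m
}

#' Distance between two PseAAC vectors
#'
#' @param x,y Encoded vectors of equal length.
#' @param method `"euclidean"` (default) or `"cosine"` (1 minus the cosine
#'   similarity).
#' @return A single non-negative real.
#' @export
pseaac_distance <- function(x, y, method = c("euclidean", "cosine")) {
  method <- match.arg(method)
  switch(method,
    euclidean = sqrt(sum((x - y)^2)),
    cosine = 1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  )
}

#' Nearest-neighbour prediction on pseudo amino acid composition
#'
#' Encodes the query and every training sequence (unless precomputed
#' `encodings` are given) and copies the label set of the training protein
#' at minimal distance, ties broken by lexicographic id.
#'
#' @param training Labelled protein table (all sequences encodable).
#' @param query One-row protein table with a sequence.
#' @param encodings Optional matrix from [encode_pseaac_dataset()]
#'   covering training (and optionally the query) ids.
#' @inheritParams encode_pseaac
#' @param distance Distance method, see [pseaac_distance()].
#' @return A one-row prediction tibble with `stage = "nna"`.
#' @export
predict_by_nna <- function(training, query, encodings = NULL, lambda = 50,
                           w = 0.15, distance = "euclidean") {
  validate_proteins(training, require_labels = TRUE)
  qid <- query$id[[1]]
  cand <- setdiff(training$id, qid)
  if (length(cand) == 0) {
    stop("no training candidates", call. = FALSE)
  }
  if (is.null(encodings)) {
    encodings <- encode_pseaac_dataset(
      dplyr::bind_rows(training[training$id %in% cand, c("id", "sequence")],
                       tibble::tibble(id = qid,
                                      sequence = query$sequence[[1]])),
      lambda = lambda, w = w
    )
  }
  if (!qid %in% rownames(encodings)) {
    stop("query ", qid, " missing from encodings", call. = FALSE)
  }
  qx <- encodings[qid, ]
  d <- vapply(cand, function(cid) {
    pseaac_distance(qx, encodings[cid, ], method = distance)
  }, numeric(1))
  nearest <- sort(cand[d == min(d)])[1]
  labels <- training$types[[match(nearest, training$id)]]
  prediction_row(qid, labels, "nna",
                 detail = sprintf("nearest=%s dist=%.4g", nearest, min(d)))
}
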