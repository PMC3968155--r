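# Independent oracles, deliberately coded against the definitions rather
# than reusing any package internals: a full-DP affine-gap local
# alignment (Gotoh), and exhaustive simple-path enumeration for shortest
# distances.

# BLOSUM62 lookup shared by the oracle (values via Biostrings data; the
# oracle only borrows the matrix constants, not any alignment code).
blosum62_matrix <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# Smith-Waterman with affine gaps: a gap of length k costs
# gap_open + k * gap_extend. Plain O(mn) dynamic program over three
# state matrices with local reset at 0.
sw_oracle <- function(a, b, gap_open = 11, gap_extend = 1,
                      mat = blosum62_matrix) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a)
  n <- length(b)
  H <- matrix(0, m + 1, n + 1)  # best ending in a match/mismatch or fresh
  E <- matrix(-Inf, m + 1, n + 1)  # gap in a (consuming b)
  F <- matrix(-Inf, m + 1, n + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(E[i, j - 1] - gap_extend,
                     H[i, j - 1] - gap_open - gap_extend)
      F[i, j] <- max(F[i - 1, j] - gap_extend,
                     H[i - 1, j] - gap_open - gap_extend)
      s <- mat[a[i - 1], b[j - 1]]
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive single-source shortest distances by enumerating all simple
# paths (adjacency as a named list of data frames with `to`, `w`).
all_paths_oracle <- function(edges, source, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    rows <- edges$a == v | edges$b == v
    data.frame(to = ifelse(edges$a[rows] == v, edges$b[rows],
                           edges$a[rows]),
               w = edges$w[rows], stringsAsFactors = FALSE)
  })
  best <- stats::setNames(rep(Inf, length(nodes)), nodes)
  best[source] <- 0
  walk <- function(v, dist, visited) {
    nb <- adj[[v]]
    for (k in seq_len(nrow(nb))) {
      u <- nb$to[k]
      if (u %in% visited) next
      d2 <- dist + nb$w[k]
      if (d2 < best[u]) best[u] <<- d2
      walk(u, d2, c(visited, u))
    }
  }
  walk(source, 0, source)
  best
}

random_aa_string <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# Random interaction table on `n` nodes (STRING-scale scores).
random_interactions <- function(n, p_edge = 0.4) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  tibble::tibble(a = pairs[1, keep], b = pairs[2, keep],
                 score = sample(1:1000, sum(keep), replace = TRUE))
}
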