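# Synthetic benchmark generator: homologous families of mutated copies
# of a common ancestor sequence, each family carrying a shared label set
# of 1-3 of the six types, embedded in a label-assortative interaction
# network with STRING-scale confidence scores. Every stage of the
# cascade can be exercised offline against planted ground truth.

#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the structure of the study's datasets at desk
#' scale: a few hundred proteins in homologous families, label
#' multiplicities dominated by single-type proteins with a mean of about
#' 1.035 types per protein (so top-t = 2), and integer confidence scores
#' on the STRING 0--1000 scale.
#'
#' @param n_proteins Number of family proteins (default 200).
#' @param n_families Number of homologous families; sizes are balanced
#'   (default 40, so families of 5).
#' @param sequence_length Ancestor sequence length (default 120; must
#'   exceed 50 so PseAAC encoding at lambda = 50 is defined).
#' @param mutation_rate Per-site substitution probability applied
#'   independently to each family member (default 0.05; 0 plants exact
#'   duplicates).
#' @param label_multiplicity Probabilities of a family carrying 1, 2 or 3
#'   types (default `c(0.97, 0.025, 0.005)`, mean 1.035).
#' @param p_same Probability of an edge between two proteins with
#'   identical label sets (default 0.3).
#' @param p_diff Probability of an edge between two proteins with
#'   differing label sets (default 0.01; must not exceed `p_same`).
#' @param confidence_range Integer confidence score range (default
#'   `c(150, 999)`).
#' @param n_orphans Additional singleton proteins with their own label
#'   sets and no family (default 0); targets for decoy homologs.
#' @param decoy_fraction Fraction of `n_proteins` added as decoy
#'   homologs: proteins whose sequence is a heavily mutated copy of a
#'   target (orphans first) but whose label set is disjoint from the
#'   target's (default 0).
#' @param decoy_mutation_rate Per-site substitution rate for decoy
#'   sequences (default 0.9, leaving only weak residual similarity).
#' @param seed Optional RNG seed stored in the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_proteins = 200, n_families = 40,
                         sequence_length = 120, mutation_rate = 0.05,
                         label_multiplicity = c(0.97, 0.025, 0.005),
                         p_same = 0.3, p_diff = 0.01,
                         confidence_range = c(150, 999), n_orphans = 0,
                         decoy_fraction = 0, decoy_mutation_rate = 0.9,
                         seed = NULL) {
  probs <- c(mutation_rate, label_multiplicity, p_same, p_diff,
             decoy_fraction, decoy_mutation_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all rates and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p_same < p_diff) {
    stop("p_same must be at least p_diff (label assortativity)",
         call. = FALSE)
  }
  if (sequence_length <= 50) {
    stop("sequence_length must exceed 50", call. = FALSE)
  }
  if (n_families > n_proteins || n_families < 1) {
    stop("need 1 <= n_families <= n_proteins", call. = FALSE)
  }
  if (abs(sum(label_multiplicity) - 1) > 1e-9) {
    stop("label_multiplicity must sum to 1", call. = FALSE)
  }
  if (confidence_range[1] <= 0 || confidence_range[2] > 1000 ||
      confidence_range[1] > confidence_range[2]) {
    stop("confidence_range must lie within (0, 1000]", call. = FALSE)
  }
  structure(
    list(n_proteins = n_proteins, n_families = n_families,
         sequence_length = sequence_length, mutation_rate = mutation_rate,
         label_multiplicity = label_multiplicity, p_same = p_same,
         p_diff = p_diff, confidence_range = confidence_range,
         n_orphans = n_orphans, decoy_fraction = decoy_fraction,
         decoy_mutation_rate = decoy_mutation_rate, seed = seed),
    class = "synth_config"
  )
}

random_sequence <- function(length) {
  paste(sample(AA_ORDER, length, replace = TRUE), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  if (rate == 0) {
    return(sequence)
  }
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ORDER, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

sample_label_set <- function(multiplicity_probs) {
  m <- sample(seq_along(multiplicity_probs), 1, prob = multiplicity_probs)
  sort(sample(1:6, m))
}

#' Generate a synthetic labelled dataset with an interaction network
#'
#' Families receive a random ancestor sequence and a shared label set;
#' members are independently mutated copies. Optional orphans are
#' unrelated singletons, and optional decoys are heavily mutated copies
#' of a target carrying a disjoint label set (planted wrong homologs for
#' E-value trade-off experiments). Edges are drawn with probability
#' `p_same` between proteins with identical label sets and `p_diff`
#' otherwise; confidences are uniform integers in `confidence_range`.
#' Fully reproducible from the seed.
#'
#' @param config A [synth_config()].
#' @param seed RNG seed (default: the one stored in the config, else the
#'   current RNG state is used as-is).
#' @return A list with elements `proteins` (labelled protein table),
#'   `interactions`, `truth` (id, family, is_orphan, is_decoy,
#'   decoy_target) and `config`.
#' @export
generate_dataset <- function(config = synth_config(), seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n <- config$n_proteins
  nf <- config$n_families
  # balanced family sizes: floor(n/nf) each, remainder spread over the
  # first families
  sizes <- rep(n %/% nf, nf) + c(rep(1, n %% nf), rep(0, nf - n %% nf))
  family <- rep(seq_len(nf), times = sizes)
  ancestors <- vapply(seq_len(nf), function(i) {
    random_sequence(config$sequence_length)
  }, character(1))
  fam_labels <- lapply(seq_len(nf), function(i) {
    sample_label_set(config$label_multiplicity)
  })
  ids <- sprintf("SYN%04d", seq_len(n))
  sequences <- vapply(seq_len(n), function(i) {
    mutate_sequence(ancestors[family[i]], config$mutation_rate)
  }, character(1))
  types <- fam_labels[family]
  truth <- tibble::tibble(id = ids, family = family, is_orphan = FALSE,
                          is_decoy = FALSE, decoy_target = NA_character_)
  if (config$n_orphans > 0) {
    oid <- sprintf("ORP%04d", seq_len(config$n_orphans))
    ids <- c(ids, oid)
    sequences <- c(sequences, vapply(seq_len(config$n_orphans),
                                     function(i) {
      random_sequence(config$sequence_length)
    }, character(1)))
    types <- c(types, lapply(seq_len(config$n_orphans), function(i) {
      sample_label_set(config$label_multiplicity)
    }))
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(id = oid, family = NA_integer_, is_orphan = TRUE,
                     is_decoy = FALSE, decoy_target = NA_character_)
    )
  }
  n_decoys <- round(config$decoy_fraction * n)
  if (n_decoys > 0) {
    # decoys target orphans first, then family proteins, cycling
    target_pool <- c(truth$id[truth$is_orphan], truth$id[!truth$is_orphan])
    targets <- rep(target_pool, length.out = n_decoys)
    did <- sprintf("DEC%04d", seq_len(n_decoys))
    dseq <- character(n_decoys)
    dtypes <- vector("list", n_decoys)
    for (i in seq_len(n_decoys)) {
      ti <- match(targets[i], ids)
      dseq[i] <- mutate_sequence(sequences[ti],
                                 config$decoy_mutation_rate)
      # disjoint label set, same multiplicity distribution as families
      pool <- setdiff(1:6, types[[ti]])
      m <- sample(seq_along(config$label_multiplicity), 1,
                  prob = config$label_multiplicity)
      dtypes[[i]] <- sort(sample(pool, min(m, length(pool))))
    }
    ids <- c(ids, did)
    sequences <- c(sequences, dseq)
    types <- c(types, dtypes)
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(id = did, family = NA_integer_, is_orphan = FALSE,
                     is_decoy = TRUE, decoy_target = targets)
    )
  }
  proteins <- tibble::tibble(id = ids, sequence = sequences, types = types)
  interactions <- sample_assortative_edges(proteins, config)
  list(proteins = proteins, interactions = interactions, truth = truth,
       config = config)
}

sample_assortative_edges <- function(proteins, config) {
  n <- nrow(proteins)
  if (n < 2) {
    return(tibble::tibble(a = character(0), b = character(0),
                          score = numeric(0)))
  }
  pairs <- utils::combn(n, 2)
  key <- vapply(proteins$types, function(t) paste(t, collapse = ","),
                character(1))
  same <- key[pairs[1, ]] == key[pairs[2, ]]
  p_edge <- ifelse(same, config$p_same, config$p_diff)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) {
    return(tibble::tibble(a = character(0), b = character(0),
                          score = numeric(0)))
  }
  a <- proteins$id[pairs[1, keep]]
  b <- proteins$id[pairs[2, keep]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  score <- sample(seq(config$confidence_range[1],
                      config$confidence_range[2]),
                  sum(keep), replace = TRUE)
  dplyr::arrange(tibble::tibble(a = a, b = b, score = as.numeric(score)),
                 .data$a, .data$b)
}

#' Write a generated dataset as plain-text fixture files
#'
#' Emits `proteins.fasta`, `annotations.tsv` and `interactions.tsv` in the
#' package's interchange formats; reading them back with [read_fasta()],
#' [read_annotations()] / [add_annotations()] and [read_interactions()]
#' reproduces the tables exactly.
#'
#' @param dir Writable directory (created if missing).
#' @param proteins Labelled protein table.
#' @param interactions Interaction table.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(dir, proteins, interactions) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    annotations = file.path(dir, "annotations.tsv"),
    interactions = file.path(dir, "interactions.tsv")
  )
  write_fasta(proteins, paths[["fasta"]])
  write_annotations(proteins, paths[["annotations"]])
  write_interactions(interactions, paths[["interactions"]])
  invisible(paths)
}

#' Read a fixture directory back into tables
#'
#' @param dir Directory written by [write_fixture()].
#' @return A list with `proteins` (annotated) and `interactions`.
#' @export
read_fixture <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  proteins <- add_annotations(proteins, ann)
  inter_path <- file.path(dir, "interactions.tsv")
  interactions <- if (file.size(inter_path) > 0) {
    read_interactions(inter_path, scale = "raw1000")
  } else {
    tibble::tibble(a = character(0), b = character(0), score = numeric(0))
  }
  list(proteins = proteins[, c("id", "sequence", "types")],
       interactions = interactions)
}
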