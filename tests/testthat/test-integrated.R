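test_that("exactly one cascade stage fires, in homology > network > shortest order", {
  training <- make_proteins(c("t1", "t2", "t3"), list(3, 4, 1))
  inter <- make_interactions(c("q", "t2"), c("t2", "t3"), c(700, 600))
  good_hit <- tibble::tibble(query_id = "q", subject_id = "t1",
                             score = 300, bitscore = 300, evalue = 1e-40)
  # a passing homolog wins even though interactions exist
  p1 <- predict_integrated(training, list(id = "q"), inter, hits = good_hit)
  expect_equal(p1$stage, "homology")
  expect_equal(p1$types[[1]], 3L)
  # no homolog but a direct partner -> network
  no_hit <- good_hit
  no_hit$evalue <- 5
  p2 <- predict_integrated(training, list(id = "q"), inter, hits = no_hit)
  expect_equal(p2$stage, "network")
  expect_equal(p2$types[[1]], 4L)
  # no homolog, no direct partner, reachable in 2 hops -> shortest distance
  inter2 <- make_interactions(c("q", "x"), c("x", "t3"), c(900, 800))
  p3 <- predict_integrated(training, list(id = "q"), inter2, hits = no_hit)
  expect_equal(p3$stage, "shortest_distance")
  expect_equal(p3$types[[1]], 1L)
  # labels are never empty
  expect_true(all(lengths(list(p1$types[[1]], p2$types[[1]],
                               p3$types[[1]])) > 0))
})

test_that("cascade stage counts partition any dataset", {
  withr::with_seed(31, {
    d <- generate_dataset(
      synth_config(n_proteins = 40, n_families = 10, mutation_rate = 0.4,
                   p_same = 0.5, p_diff = 0.02),
      seed = 31
    )
  })
  ev <- loo_evaluate(d$proteins, d$interactions, method = "integrated")
  expect_equal(sum(ev$stage_summary$n_annotated), nrow(d$proteins))
  expect_equal(ev$n_unannotated, 0L)
})

test_that("cascade degenerates sensibly with empty interactions or no sequences", {
  withr::with_seed(8, {
    d <- generate_dataset(
      synth_config(n_proteins = 12, n_families = 4, mutation_rate = 0),
      seed = 8
    )
  })
  empty <- make_interactions(character(0), character(0), numeric(0))
  ev <- loo_evaluate(d$proteins, empty, method = "integrated")
  expect_true(all(ev$records$stage %in% c("homology", "shortest_distance")))
  # identical family members -> homology annotates everything here
  expect_true(all(ev$records$stage == "homology"))

  noseq <- d$proteins
  noseq$sequence <- NA_character_
  ev2 <- loo_evaluate(noseq, d$interactions, method = "integrated")
  expect_true(all(ev2$records$stage %in% c("network", "shortest_distance")))
})

test_that("RWC combines min-max normalized components", {
  training <- make_proteins(c("c1", "c2"), list(1, 2))
  # hand-set raw components: c1 = (best s, worst w, worst sd),
  # c2 = (worst s, best w, best sd)
  hits <- tibble::tibble(query_id = "q", subject_id = c("c1", "c2"),
                         score = c(50, 10), bitscore = c(50, 10),
                         evalue = c(1e-5, 1))
  inter <- make_interactions(c("q", "q", "c1"), c("c1", "c2", "c2"),
                             c(100, 900, 500))
  sc <- rwc_scores(training, list(id = "q"), inter, hits = hits)
  sc <- sc[order(sc$candidate), ]
  # c1: s_hat 1, w_hat 0, sd 900 -> inv 0 => S = 1/3
  # c2: s_hat 0, w_hat 1, sd 100 -> inv 1 => S = 2/3
  expect_equal(sc$rwc, c(1 / 3, 2 / 3))
  p <- predict_by_rwc(training, list(id = "q"), inter, hits = hits)
  expect_equal(p$types[[1]], 2L)

  # a candidate best on all three components scores exactly 1
  hits2 <- tibble::tibble(query_id = "q", subject_id = c("c1", "c2"),
                          score = c(80, 10), bitscore = c(80, 10),
                          evalue = c(1e-9, 1))
  inter2 <- make_interactions(c("q", "q"), c("c1", "c2"), c(900, 200))
  sc2 <- rwc_scores(training, list(id = "q"), inter2, hits = hits2)
  sc2 <- sc2[order(sc2$candidate), ]
  expect_equal(sc2$rwc[1], 1)
  expect_equal(sc2$rwc[2], 0)
})

test_that("RWC is invariant to affine rescaling of a raw component", {
  training <- make_proteins(c("c1", "c2", "c3"), list(1, 2, 3))
  hits <- tibble::tibble(query_id = "q", subject_id = c("c1", "c2", "c3"),
                         score = c(50, 30, 10),
                         bitscore = c(50, 30, 10),
                         evalue = c(1e-6, 1e-3, 0.5))
  inter <- make_interactions(rep("q", 3), c("c1", "c2", "c3"),
                             c(300, 600, 900))
  s1 <- rwc_scores(training, list(id = "q"), inter, hits = hits)
  hits2 <- hits
  hits2$bitscore <- hits$bitscore * 7 + 100 # affine rescale
  s2 <- rwc_scores(training, list(id = "q"), inter, hits = hits2)
  expect_equal(s1$rwc, s2$rwc)
  expect_error(rwc_scores(training, list(id = "q"), inter,
                          weights = c(-1, 1, 1)), "non-negative")
})

test_that("RWC errors only when every component is undefined everywhere", {
  training <- make_proteins(c("c1", "c2"), list(1, 2),
                            sequences = c(NA, NA))
  empty <- make_interactions(character(0), character(0), numeric(0))
  expect_error(rwc_scores(training, list(id = "q"), empty, hits = NULL),
               "undefined")
})

test_that("an RWC-favoured wrong neighbour beats a correct homolog (anecdote analogue)", {
  # the query's true type is multi-pass; its best homolog agrees, but a
  # high-confidence short-distance neighbour carries single-pass type I
  # and wins the combined score
  training <- make_proteins(c("hom", "wrong"), list(3, 5))
  hits <- tibble::tibble(query_id = "q", subject_id = c("hom", "wrong"),
                         score = c(120, 100), bitscore = c(120, 100),
                         evalue = c(1e-12, 1e-9))
  inter <- make_interactions(c("q"), c("wrong"), 950)
  rwc <- predict_by_rwc(training, list(id = "q"), inter, hits = hits)
  expect_equal(rwc$types[[1]], 5L) # RWC errs
  hom <- predict_by_homology(training, list(id = "q"), hits = hits)
  expect_equal(hom$types[[1]], 3L) # the cascade's homology stage is right
})
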