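test_that("precision and recall follow the multi-label set definitions", {
  r <- make_records(list(c(1, 2)), list(c(2, 3)))
  pr <- precision_recall(r)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)
  # predicting a superset always gives recall 1
  sup <- make_records(list(1, c(2, 3)), list(1:6, 1:6))
  expect_equal(precision_recall(sup)$recall, 1)
  # predicting a non-empty subset always gives precision 1
  sub <- make_records(list(c(1, 2, 3), c(4, 5)), list(1, 4))
  expect_equal(precision_recall(sub)$precision, 1)
  expect_error(precision_recall(make_records(list(), list())), "no annotated")
})

test_that("accuracy rewards exact matches and penalizes over-prediction", {
  exact <- make_records(list(1, c(2, 3)), list(1, c(2, 3)))
  expect_equal(multilabel_accuracy(exact), 1)
  expect_equal(multilabel_accuracy(exact, variant = "jaccard"), 1)
  # one spurious extra type: 1 - 1/2 under the default, 1/2 under jaccard
  over <- make_records(list(1), list(c(1, 2)))
  expect_equal(multilabel_accuracy(over), 0.5)
  expect_equal(multilabel_accuracy(over, variant = "jaccard"), 0.5)
  # disjoint prediction: -1 under the default, 0 under jaccard
  wrong <- make_records(list(1), list(2))
  expect_equal(multilabel_accuracy(wrong), -1)
  expect_equal(multilabel_accuracy(wrong, variant = "jaccard"), 0)
  expect_error(multilabel_accuracy(exact, variant = "nope"))
})

test_that("per-record accuracy bounds hold and both variants peak only at exact matches", {
  withr::with_seed(40, {
    for (k in 1:50) {
      a <- sort(sample(1:6, sample(1:3, 1)))
      p <- sort(sample(1:6, sample(1:6, 1)))
      r <- make_records(list(a), list(p))
      acc <- multilabel_accuracy(r)
      accj <- multilabel_accuracy(r, variant = "jaccard")
      expect_gte(acc, -1); expect_lte(acc, 1)
      expect_gte(accj, 0); expect_lte(accj, 1)
      if (setequal(a, p)) {
        expect_equal(acc, 1); expect_equal(accj, 1)
      } else {
        expect_lt(acc, 1); expect_lt(accj, 1)
      }
    }
  })
})

test_that("c/p/e classification partitions each multiplicity group", {
  r <- make_records(
    list(c(1, 2), c(1, 2), 1, c(1, 2, 3), 4),
    list(c(1, 2), 1, 3, c(1, 2, 3), c(4, 5))
  )
  bd <- breakdown_by_type_count(r)
  expect_equal(bd$n, bd$c + bd$p + bd$e)
  g1 <- bd[bd$n_types == 1, ]
  expect_equal(c(g1$c, g1$p, g1$e), c(0L, 1L, 1L))
  g2 <- bd[bd$n_types == 2, ]
  expect_equal(c(g2$c, g2$p, g2$e), c(1L, 1L, 0L))
  g3 <- bd[bd$n_types == 3, ]
  expect_equal(c(g3$c, g3$p, g3$e), c(1L, 0L, 0L))
})

test_that("leave-one-out produces one record per protein and exact planted recovery", {
  withr::with_seed(23, {
    d <- generate_dataset(
      synth_config(n_proteins = 20, n_families = 5, mutation_rate = 0),
      seed = 23
    )
  })
  ev <- loo_evaluate(d$proteins, d$interactions, method = "homology")
  expect_s3_class(ev, "memtype_eval")
  expect_equal(nrow(tidy(ev)), 20L)
  g <- glance(ev)
  # every protein has an exact duplicate family member
  expect_equal(g$acc, 1)
  expect_equal(g$n_unannotated, 0L)
  # reproducibility: identical inputs give identical reports
  ev2 <- loo_evaluate(d$proteins, d$interactions, method = "homology")
  expect_equal(tidy(ev2), tidy(ev))
})

test_that("abstaining single methods report NU separately from Acc", {
  # two unrelated random proteins: nothing passes the homology gate
  withr::with_seed(29, {
    prot <- make_proteins(c("a", "b"), list(1, 2),
                          sequences = replicate(2, random_aa_string(60)))
  })
  ev <- loo_evaluate(prot, method = "homology", evalue_cutoff = 1e-30)
  g <- glance(ev)
  expect_equal(g$n_unannotated, 2L)
  expect_true(is.na(g$acc))
})

test_that("the E-value sweep is NU-monotone and reproduces the trade-off direction", {
  withr::with_seed(47, {
    d <- generate_dataset(
      synth_config(n_proteins = 30, n_families = 10, mutation_rate = 0,
                   n_orphans = 6, decoy_fraction = 0.2),
      seed = 47
    )
  })
  hits <- homology_hits(d$proteins)
  sw <- evalue_sweep(d$proteins, c(1e-10, 0.01, 10), hits = hits)
  expect_equal(sw$cutoff, c(1e-10, 0.01, 10))
  # loosening the gate can only annotate more
  expect_true(all(diff(sw$n_unannotated) <= 0))
  # decoys and random hits admitted past 0.01 carry wrong labels
  expect_gt(sw$acc[sw$cutoff == 0.01], sw$acc[sw$cutoff == 10])
  # a cutoff below every E-value annotates nothing and reports NA metrics
  sw0 <- evalue_sweep(d$proteins, c(1e-300, 1e-290), hits = hits)
  expect_equal(sw0$n_unannotated[1], nrow(d$proteins))
  expect_true(is.na(sw0$acc[1]))
  expect_error(evalue_sweep(d$proteins, 0.01), "two cutoffs")
})

test_that("evaluation reports expose tidy records and glance summaries", {
  withr::with_seed(90, {
    d <- generate_dataset(
      synth_config(n_proteins = 16, n_families = 4, mutation_rate = 0.2),
      seed = 90
    )
  })
  ev <- loo_evaluate(d$proteins, d$interactions, method = "integrated")
  rec <- tidy(ev)
  expect_named(rec, c("id", "actual", "predicted", "stage", "annotated",
                      "fallback", "detail"))
  g <- glance(ev)
  expect_equal(g$n, 16L)
  expect_equal(g$n_annotated + g$n_unannotated, 16L)
  expect_output(print(ev), "Leave-one-out")
})
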