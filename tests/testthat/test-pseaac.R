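test_that("the property table holds the published values", {
  p <- aa_properties()
  expect_equal(nrow(p), 20L)
  expect_equal(p$polarity[p$aa == "A"], -0.591)
  expect_equal(p$electrostatic_charge[p$aa == "R"], 2.897)
  expect_equal(p$molecular_volume[p$aa == "S"], -4.760)
  expect_equal(p$codon_diversity[p$aa == "W"], -2.128)
  expect_equal(p$secondary_structure[p$aa == "P"], 2.081)
})

test_that("property standardization yields mean 0, sd 1 and preserves ranks", {
  p <- aa_properties()
  for (col in setdiff(names(p), "aa")) {
    f <- standardize_property(p[[col]])
    expect_equal(mean(f), 0, tolerance = 1e-12)
    expect_equal(stats::sd(f), 1, tolerance = 1e-12)
    expect_equal(order(f), order(p[[col]]))
  }
  # K has the largest polarity (1.831), so also the largest standardized value
  ps <- aa_properties(standardized = TRUE)
  expect_equal(ps$aa[which.max(ps$polarity)], "K")
  expect_error(standardize_property(rep(1, 20)), "variance")
  expect_error(standardize_property(1:5), "20")
})

test_that("correlation factors match their closed forms and a brute-force oracle", {
  vals <- stats::setNames(aa_properties()$polarity, aa_properties()$aa)
  # homopolymer: all differences zero
  expect_equal(correlation_factors(strrep("A", 60), vals, lambda = 5),
               rep(0, 5))
  # alternating ACAC...: theta_1 = (F(C) - F(A))^2, theta_2 = 0
  f <- stats::setNames(standardize_property(unname(vals)), names(vals))
  th <- correlation_factors(strrep("AC", 30), vals, lambda = 2)
  expect_equal(th, c((f[["C"]] - f[["A"]])^2, 0))
  # random sequences vs a directly-indexed double loop
  withr::with_seed(55, {
    for (k in 1:5) {
      s <- random_aa_string(60)
      chars <- strsplit(s, "")[[1]]
      want <- vapply(1:10, function(j) {
        acc <- 0
        for (i in 1:(60 - j)) {
          acc <- acc + (f[[chars[i + j]]] - f[[chars[i]]])^2
        }
        acc / (60 - j)
      }, numeric(1))
      expect_equal(correlation_factors(s, vals, lambda = 10), want)
    }
  })
  expect_error(correlation_factors(strrep("A", 40), vals, lambda = 50),
               "too short")
})

test_that("PseAAC vectors have 270 non-negative components summing to 1", {
  withr::with_seed(66, {
    for (k in 1:20) {
      x <- encode_pseaac(random_aa_string(sample(51:200, 1)))
      expect_length(x, 270)
      expect_true(all(x >= 0))
      expect_equal(sum(x), 1, tolerance = 1e-9)
    }
  })
})

test_that("limit cases: w = 0 reduces to plain composition; homopolymers are one-hot", {
  s <- random_aa_string(80)
  x0 <- encode_pseaac(s, w = 0)
  expect_equal(sum(x0[1:20]), 1, tolerance = 1e-12)
  expect_true(all(x0[21:270] == 0))
  xh <- encode_pseaac(strrep("L", 70))
  expect_equal(unname(xh[1:20]), c(rep(0, 9), 1, rep(0, 10))) # L is 10th
  expect_true(all(xh[21:270] == 0))
})

test_that("shuffling a sequence changes theta but not the composition block", {
  withr::with_seed(12, {
    s <- random_aa_string(90)
    chars <- strsplit(s, "")[[1]]
    s2 <- paste(sample(chars), collapse = "")
  })
  x1 <- encode_pseaac(s)
  x2 <- encode_pseaac(s2)
  # raw frequencies identical; normalization differs only through theta
  f1 <- x1[1:20] / sum(x1[1:20])
  f2 <- x2[1:20] / sum(x2[1:20])
  expect_equal(unname(f1), unname(f2))
  expect_false(isTRUE(all.equal(x1[21:270], x2[21:270])))
})

test_that("non-standard residues are dropped with a warning", {
  expect_warning(x <- encode_pseaac(paste0(strrep("AC", 30), "XXU")),
                 "non-standard")
  expect_length(x, 270)
  expect_equal(sum(x), 1, tolerance = 1e-9)
})

test_that("the NNA baseline returns the nearest training protein's labels", {
  withr::with_seed(14, {
    seqs <- replicate(3, random_aa_string(60))
  })
  training <- make_proteins(c("t1", "t2", "t3"), list(3, c(1, 2), 5),
                            sequences = seqs)
  # an identical sequence is at distance zero
  q <- tibble::tibble(id = "q", sequence = seqs[2])
  p <- predict_by_nna(training, q)
  expect_equal(p$types[[1]], c(1L, 2L))
  # argmin agrees with exhaustive pairwise distances
  withr::with_seed(19, {
    qs <- tibble::tibble(id = "q2", sequence = random_aa_string(60))
  })
  enc <- encode_pseaac_dataset(dplyr::bind_rows(training[, 1:2], qs))
  d <- apply(enc[1:3, ], 1, function(r) sqrt(sum((r - enc["q2", ])^2)))
  p2 <- predict_by_nna(training, qs)
  expect_equal(p2$types[[1]],
               training$types[[which.min(d)]])
  # metric axioms on the encoded vectors
  expect_equal(pseaac_distance(enc[1, ], enc[1, ]), 0)
  expect_equal(pseaac_distance(enc[1, ], enc[2, ]),
               pseaac_distance(enc[2, ], enc[1, ]))
  expect_equal(pseaac_distance(enc[1, ], enc[2, ], method = "cosine"),
               pseaac_distance(enc[2, ], enc[1, ], method = "cosine"))
  expect_error(predict_by_nna(training,
                              tibble::tibble(id = "s",
                                             sequence = strrep("A", 20))),
               "too short")
})
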