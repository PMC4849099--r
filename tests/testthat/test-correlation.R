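test_that("contingency tables enumerate sentences by presence", {
  map <- build_tables(four_cell_sentences(), concept_set("C"))
  t_fC <- get_table(map, "f", "C")
  expect_equal(c(t_fC$a, t_fC$b, t_fC$c, t_fC$d), c(1, 1, 1, 1))

  # feature and concept in every sentence -> (a = N, 0, 0, 0)
  sents <- lapply(1:4, function(i)
    make_sentence(c("f", "f", "z"), gold = c("C", "C"), id = paste0("u", i)))
  t_all <- get_table(build_tables(sents, concept_set("C")), "f", "C")
  expect_equal(c(t_all$a, t_all$b, t_all$c, t_all$d), c(4, 0, 0, 0))

  empty <- build_tables(list(), concept_set("C"))
  expect_identical(nrow(as.data.frame(empty)), 0L)
})

test_that("Yates chi-square matches its printed closed form on spot values", {
  expect_equal(yates_chi_square(contingency_table(5, 5, 5, 5)), 0.2)
  expect_equal(yates_chi_square(contingency_table(10, 0, 0, 10)), 16.2)
  expect_error(yates_chi_square(contingency_table(0, 0, 5, 5)), "degenerate")
})

test_that("the three correlation measures agree with independent oracles", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      cells <- sample(1:40, 4L, replace = TRUE)
      t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      expect_equal(yates_chi_square(t), do.call(oracle_yates, as.list(cells)),
                   tolerance = 1e-10)
      expect_equal(relative_risk(t), do.call(oracle_relative_risk, as.list(cells)),
                   tolerance = 1e-10)
      expect_equal(odds_ratio(t), do.call(oracle_odds_ratio, as.list(cells)),
                   tolerance = 1e-10)
    }
  })
})

test_that("relative risk and odds ratio handle balanced and zero-cell tables", {
  expect_equal(relative_risk(contingency_table(5, 5, 5, 5)), 1)
  expect_equal(relative_risk(contingency_table(8, 2, 2, 8)), 4)
  expect_equal(relative_risk(contingency_table(1, 1, 0, 2)), 3) # +0.5 correction
  expect_equal(odds_ratio(contingency_table(5, 5, 5, 5)), 1)
  expect_equal(odds_ratio(contingency_table(9, 1, 1, 9)), 81)
})

test_that("odds ratio is reciprocal-symmetric and monotone in a", {
  withr::with_seed(7, {
    for (i in 1:100) {
      cells <- sample(1:30, 4L, replace = TRUE)
      or1 <- odds_ratio(do.call(contingency_table, as.list(cells)))
      or2 <- odds_ratio(contingency_table(cells[3], cells[4], cells[1], cells[2]))
      expect_equal(or1 * or2, 1, tolerance = 1e-12)
    }
  })
  ors <- vapply(1:20, function(a) odds_ratio(contingency_table(a, 4, 3, 7)), 0)
  expect_true(all(diff(ors) > 0))
})

test_that("equal-proportion tables score 1 under risk and odds measures", {
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- sample(1:20, 1); c_ <- sample(1:20, 1); r <- sample(1:4, 1)
      t <- contingency_table(a, a * r, c_, c_ * r)
      expect_equal(relative_risk(t), 1)
      expect_equal(odds_ratio(t), 1)
    }
  })
})

test_that("softmax is a shift-invariant distribution", {
  expect_equal(unname(softmax(c(1, 1, 1, 1))), rep(0.25, 4))
  expect_equal(unname(softmax(c(k1 = 0, k2 = log(3)))), c(0.25, 0.75))
  expect_error(softmax(numeric()), "at least one")
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- rnorm(sample(1:8, 1), sd = 10)
      p <- softmax(x)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p > 0 & p < 1 | length(x) == 1))
      expect_equal(softmax(x + 17.3), p, tolerance = 1e-12)
    }
  })
})

test_that("fitted models rank the perfectly-correlated feature first", {
  # kwa occurs iff A, kwb iff B
  sents <- two_concept_sentences()
  cs <- concept_set(c("A", "B"))
  for (method in c("chi2_yates", "relative_risk", "odds_ratio")) {
    m <- fit_correlation_model(sents, cs, method = method)
    expect_identical(rownames(m$W)[which.max(m$W[, "A"])], "kwa")
    expect_identical(rownames(m$W)[which.max(m$W[, "B"])], "kwb")
  }
  expect_error(fit_correlation_model(sents, cs, method = "bogus"))
  expect_error(fit_correlation_model(list(), cs), "no labeled sentences")
})

test_that("feature probabilities are Eq-consistent softmax values", {
  sents <- four_cell_sentences()
  cs <- concept_set("C")
  m <- fit_correlation_model(sents, cs, method = "chi2_yates")
  # W on the enumerated (1,1,1,1) table, composed through build_tables
  expect_equal(m$W["f", "C"], yates_chi_square(contingency_table(1, 1, 1, 1)))
  # probabilities normalize over the vocabulary per concept
  p <- vapply(m$vocabulary, function(f) feature_probability(m, f, "C"), 0)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # out-of-vocabulary with OOV disabled -> 0
  expect_equal(feature_probability(m, "unseen", "C"), 0)
  # singleton vocabulary -> probability 1
  m1 <- fit_correlation_model(list(make_sentence("solo", gold = "C", id = "q1")),
                              cs)
  expect_equal(feature_probability(m1, "solo", "C"), 1)
})

test_that("two equal-weight features split probability evenly", {
  m <- make_model(matrix(c(2, 2), 2, 1, dimnames = list(c("f1", "f2"), "C")))
  expect_equal(feature_probability(m, "f1", "C"), 0.5)
  expect_equal(feature_probability(m, "f2", "C"), 0.5)
})

test_that("model serialization round-trips bit-exactly", {
  m <- fit_correlation_model(two_concept_sentences(), concept_set(c("A", "B")),
                             method = "odds_ratio")
  path <- withr::local_tempfile()
  write_correlation_model(m, path)
  m2 <- read_correlation_model(path)
  expect_identical(m2$method, m$method)
  expect_identical(sort(m2$vocabulary), sort(m$vocabulary))
  expect_identical(m2$W[m$vocabulary, m$concepts], m$W)
})
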