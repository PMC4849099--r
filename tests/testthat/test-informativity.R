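test_that("priors are MLE sentence fractions with a floor for unseen concepts", {
  cs <- concept_set(c("E1", "E2"))
  sents <- c(lapply(1:3, function(i) make_sentence("a", gold = "E1", id = paste0("p", i))),
             list(make_sentence("b", gold = "E2", id = "p4")))
  pr <- fit_prior(sents, cs)
  expect_equal(unclass(pr), c(E1 = 0.75, E2 = 0.25))

  pr1 <- fit_prior(list(make_sentence("a", gold = "E1", id = "q")), concept_set("E1"))
  expect_equal(unname(unclass(pr1)), 1)

  sents2 <- lapply(1:4, function(i) make_sentence("a", gold = "E1", id = paste0("r", i)))
  pr2 <- fit_prior(sents2, cs)
  expect_equal(pr2[["E2"]], 1e-6 / (4 + 1e-6))
  expect_gt(pr2[["E2"]], 0)
  expect_equal(sum(pr2), 1)

  expect_error(fit_prior(list(make_sentence("a", id = "z")), cs), "no annotations")
})

test_that("z scores average occurrence-counted feature probabilities", {
  m <- model_with_probs(matrix(c(0.2, 0.4, 0.4), 3, 1,
                               dimnames = list(c("u", "v", "w"), "C")))
  expect_equal(z_score(make_sentence(c("u", "v")), "C", m), 0.3)
  expect_equal(z_score(make_sentence(c("u", "u")), "C", m), 0.2) # (0.2+0.2)/2
  expect_equal(z_score(make_sentence(c("zz", "yy")), "C", m), 0)  # OOV off
  empty <- al_sentence("e", "")
  expect_equal(z_score(empty, "C", m), 0)
})

test_that("sentence likelihood is a softmax over concepts", {
  cs <- concept_set(c("A", "B"))
  # two features giving Z = (0, log 3) across concepts on a 1-token sentence
  W <- matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(c("f", "g"), c("A", "B")))
  m <- make_model(W)
  s <- make_sentence("f")
  lik <- sentence_likelihood(s, cs, m)
  expect_equal(sum(lik), 1, tolerance = 1e-12)
  expect_equal(unname(lik), c(0.5, 0.5)) # symmetric model -> uniform
  # closed form {0.25, 0.75} from z difference of log 3
  z <- c(A = 0, B = log(3))
  expect_equal(unname(softmax(z)), c(0.25, 0.75))
})

test_that("posterior is the prior-likelihood product with unit evidence", {
  prior <- structure(c(E1 = 0.6, E2 = 0.4), class = "prior_model")
  # model under which the one-token sentence "f" has Z = (0, log(7/3)),
  # hence likelihoods (0.3, 0.7)
  m <- model_with_probs(matrix(c(1e-15, 1, log(7 / 3), 1 - log(7 / 3)), 2, 2,
                               dimnames = list(c("f", "g"), c("E1", "E2"))))
  s <- make_sentence("f")
  expect_equal(concept_posterior(s, "E1", prior, m), 0.18, tolerance = 1e-9)
  expect_equal(concept_posterior(s, "E2", prior, m), 0.28, tolerance = 1e-9)
  # uniform x uniform over m concepts -> 1/m^2
  m0 <- make_model(matrix(0, 1, 2, dimnames = list("f", c("E1", "E2"))))
  prior_u <- structure(c(E1 = 0.5, E2 = 0.5), class = "prior_model")
  expect_equal(concept_posterior(make_sentence("f"), "E1", prior_u, m0), 0.25)
  # zero prior -> zero posterior
  prior_z <- structure(c(E1 = 0, E2 = 1), class = "prior_model")
  expect_equal(concept_posterior(make_sentence("f"), "E1", prior_z, m0), 0)
})

test_that("recognizer filtering zeroes recognized concepts and only those", {
  cs <- concept_set(c("E1", "E2"))
  prior <- structure(c(E1 = 0.6, E2 = 0.4), class = "prior_model")
  m <- make_model(matrix(0, 1, 2, dimnames = list("f", c("E1", "E2"))))
  s <- make_sentence("f", id = "s1")
  post <- c(E1 = 0.3, E2 = 0.2) # with this symmetric model: prior * 0.5

  none <- stub_learner(list(), c("E1", "E2"))
  both <- stub_learner(list(s1 = c("E1", "E2")), c("E1", "E2"))
  only1 <- stub_learner(list(s1 = "E1"), c("E1", "E2"))
  expect_equal(sentence_informativity(s, cs, none, prior, m), 0.5)
  expect_equal(sentence_informativity(s, cs, both, prior, m), 0)
  expect_equal(sentence_informativity(s, cs, only1, prior, m), 0.2)
  # filtering dominance
  expect_lte(sentence_informativity(s, cs, only1, prior, m),
             sentence_informativity(s, cs, none, prior, m))
})

test_that("participant informativity is delta times the mention count", {
  expect_equal(ne_informativity(make_sentence("a", ne = 0)), 0)
  expect_equal(ne_informativity(make_sentence("a", ne = 2), delta = 0.25), 0.5)
  expect_error(ne_informativity(make_sentence("a"), delta = -1), "delta")
})

test_that("OOV backoff sums similarity-weighted neighbor weights", {
  W <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(c("n1", "n2"), "C"))
  m <- make_model(W)
  prov <- similarity_table(data.frame(w1 = c("oov", "oov"), w2 = c("n1", "n2"),
                                      sim = c(0.5, 0.5)))
  expect_equal(oov_weight("oov", "C", m, prov, k = 2), 0.3)
  # k = 1 keeps only the top neighbor; the similarity tie breaks to n1
  expect_equal(oov_weight("oov", "C", m, prov, k = 1), 0.2 * 0.5)
  expect_error(oov_weight("oov", "C", m, prov, k = 0), "k must be")
  # provider without in-vocabulary neighbors -> 0
  prov2 <- similarity_table(data.frame(w1 = "oov", w2 = "elsewhere", sim = 0.9))
  expect_equal(oov_weight("oov", "C", m, prov2, k = 5), 0)
  # identical (W, sim) neighbors: W_OOV = k * w * s
  Wk <- matrix(rep(0.4, 6), 6, 1,
               dimnames = list(paste0("m", 1:6), "C"))
  mk <- make_model(Wk)
  provk <- similarity_table(data.frame(w1 = "oov", w2 = paste0("m", 1:6), sim = 0.5))
  for (k in c(1, 3, 6))
    expect_equal(oov_weight("oov", "C", mk, provk, k = k), k * 0.4 * 0.5)
})

test_that("similarity providers answer lookups and neighbor queries", {
  prov <- similarity_table(data.frame(w1 = c("a", "a", "b"),
                                      w2 = c("b", "c", "c"),
                                      sim = c(0.9, 0.2, 0.5)))
  expect_equal(sim_lookup(prov, "a", "b"), 0.9)
  expect_equal(sim_lookup(prov, "b", "a"), 0.9) # symmetric
  expect_equal(sim_lookup(prov, "a", "zzz"), 0)
  expect_equal(sim_lookup(prov, "q", "q"), 1)   # self-similarity maximal
  nb <- sim_neighbors(prov, "a", 1, c("b", "c"))
  expect_identical(names(nb), "b")

  vec_file <- withr::local_tempfile()
  writeLines(c("3 2", "x 1 0", "y 1 0", "z 0 1"), vec_file)
  wv <- read_word_vectors(vec_file)
  expect_equal(sim_lookup(wv, "x", "y"), 1, tolerance = 1e-12)
  expect_equal(sim_lookup(wv, "x", "z"), 0, tolerance = 1e-12)
  expect_identical(names(sim_neighbors(wv, "x", 1, c("y", "z"))), "y")
})

test_that("z scores use OOV backoff only for unknown unigrams when enabled", {
  W <- matrix(c(10, 0), 2, 1, dimnames = list(c("n1", "n2"), "C"))
  m <- make_model(W)
  prov <- similarity_table(data.frame(w1 = "oov", w2 = "n1", sim = 0.9))
  s <- make_sentence("oov")
  expect_equal(z_score(s, "C", m), 0)
  z_oov <- z_score(s, "C", m, sim = prov, oov_enabled = TRUE, k = 5)
  expect_gt(z_oov, 0)
  expect_lte(z_oov, 1) # probability-bounded backoff
})

test_that("combined informativity reduces to its components at corner weights", {
  cs <- concept_set(c("E1", "E2"))
  prior <- structure(c(E1 = 0.5, E2 = 0.5), class = "prior_model")
  m <- make_model(matrix(0, 1, 2, dimnames = list("f", c("E1", "E2"))))
  s <- make_sentence("f", ne = 2, id = "s1")
  none <- stub_learner(list(), c("E1", "E2"))

  cfg_ne <- informativity_config(alpha = 0, beta = 0, gamma = 1, delta = 0.25)
  expect_equal(combined_sentence_informativity(s, cfg_ne, none, prior, cs),
               ne_informativity(s, 0.25))

  cfg_ng <- informativity_config(alpha = 1, beta = 0, gamma = 0)
  expect_equal(combined_sentence_informativity(s, cfg_ng, none, prior, cs,
                                               ngram_model = m),
               sentence_informativity(s, cs, none, prior, m))

  # weighted sum of known components
  cfg <- informativity_config(alpha = 0.1, beta = 0.1, gamma = 0.8,
                              feature_kind = "combined")
  pas_m <- make_model(matrix(0, 1, 2, dimnames = list("f arg g", c("E1", "E2"))),
                      features = feature_spec("pas"))
  got <- combined_sentence_informativity(s, cfg, none, prior, cs,
                                         ngram_model = m, pas_model = pas_m)
  i_ng <- sentence_informativity(s, cs, none, prior, m)
  i_pas <- sentence_informativity(s, cs, none, prior, pas_m)
  expect_equal(got, 0.1 * i_ng + 0.1 * i_pas + 0.8 * 0.25 * 2)
  expect_error(combined_sentence_informativity(s, cfg, none, prior, cs,
                                               ngram_model = m), "PAS model")
})

test_that("combined informativity increases strictly with the mention count", {
  cs <- concept_set("E1")
  prior <- structure(c(E1 = 1), class = "prior_model")
  m <- make_model(matrix(0, 1, 1, dimnames = list("f", "E1")))
  none <- stub_learner(list(), "E1")
  cfg <- informativity_config(alpha = 0.1, beta = 0, gamma = 0.8, delta = 0.25)
  scores <- vapply(0:4, function(T_)
    combined_sentence_informativity(make_sentence("f", ne = T_, id = paste0("s", T_)),
                                    cfg, none, prior, cs, ngram_model = m), 0)
  expect_true(all(diff(scores) > 0))
})

test_that("NER mode forbids PAS features and scores with n-grams alone", {
  expect_error(informativity_config(task = "ner", feature_kind = "pas"),
               "n-gram features only")
  cs <- concept_set(c("N1", "N2"), kind = "entity")
  prior <- structure(c(N1 = 0.5, N2 = 0.5), class = "prior_model")
  m <- make_model(matrix(0, 1, 2, dimnames = list("f", c("N1", "N2"))))
  s <- make_sentence("f", ne = 3, id = "s1")
  none <- stub_learner(list(), c("N1", "N2"))
  cfg <- informativity_config(task = "ner", feature_kind = "ngram")
  # the participant term plays no role in NER mode
  expect_equal(combined_sentence_informativity(s, cfg, none, prior, cs,
                                               ngram_model = m),
               sentence_informativity(s, cs, none, prior, m))
})

test_that("document informativity is the sentence mean", {
  m <- model_with_probs(matrix(c(0.2, 0.8), 2, 1,
                               dimnames = list(c("u", "v"), "C")))
  scorer <- function(s) z_score(s, "C", m)
  doc <- make_doc("d", list("u", "v"))
  expect_equal(document_informativity(doc, scorer), 0.5)
  doc1 <- make_doc("d1", list(c("u", "u")))
  expect_equal(document_informativity(doc1, scorer), 0.2)
  doc0 <- make_doc("d0", list("zz", "yy"))
  expect_equal(document_informativity(doc0, scorer), 0)
})
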