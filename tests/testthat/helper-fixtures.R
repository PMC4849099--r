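# Shared fixtures and independent oracles.

make_sentence <- function(tokens, gold = character(), ne = 0L,
                          id = paste(tokens, collapse = "_"), pas = NULL) {
  al_sentence(id = id, text = paste(tokens, collapse = " "),
              gold_concepts = gold, pas_units = pas, ne_count = ne)
}

make_doc <- function(id, token_lists, golds = NULL, nes = NULL) {
  n <- length(token_lists)
  if (is.null(golds)) golds <- replicate(n, character(), simplify = FALSE)
  if (is.null(nes)) nes <- rep(0L, n)
  al_document(id, lapply(seq_len(n), function(k)
    make_sentence(token_lists[[k]], golds[[k]], nes[[k]],
                  id = paste0(id, ":", k))))
}

# Four-sentence enumeration corpus: feature f and concept C in all
# combinations.
four_cell_sentences <- function() {
  list(make_sentence(c("f", "x"), gold = "C", id = "s1"),
       make_sentence(c("f", "y"), gold = character(), id = "s2"),
       make_sentence(c("g", "x"), gold = "C", id = "s3"),
       make_sentence(c("g", "y"), gold = character(), id = "s4"))
}

# A tiny two-concept training corpus where each concept has its own keyword.
two_concept_sentences <- function() {
  list(make_sentence(c("kwa", "x"), gold = "A", id = "t1"),
       make_sentence(c("kwa", "y"), gold = "A", id = "t2"),
       make_sentence(c("kwb", "x"), gold = "B", id = "t3"),
       make_sentence(c("kwb", "y", "z"), gold = "B", id = "t4"),
       make_sentence(c("x", "y"), gold = character(), id = "t5"))
}

# Fabricate a fitted correlation model directly from a weight matrix, for
# unit tests that need exact feature probabilities.
make_model <- function(W, features = feature_spec("ngram", 1L)) {
  structure(list(method = "chi2_yates", features = features, W = W,
                 log_norm = apply(W, 2L, function(col) {
                   m <- max(col); m + log(sum(exp(col - m)))
                 }),
                 vocabulary = rownames(W), concepts = colnames(W),
                 clamp_yates = FALSE),
            class = "correlation_model")
}

# A weight matrix whose softmax gives chosen probabilities per concept.
model_with_probs <- function(prob_matrix) {
  make_model(log(prob_matrix))
}

# Stub recognizer with a fixed recognition table, for contract tests.
stub_learner <- function(recognized, concepts, probs = NULL) {
  structure(list(recognized = recognized, concepts = concepts, probs = probs),
            class = "stub_learner")
}
decision_values.stub_learner <- function(learner, sentence) {
  rec <- learner$recognized[[sentence$id]]
  if (is.null(rec)) rec <- character()
  stats::setNames(ifelse(learner$concepts %in% rec, 1, -1), learner$concepts)
}
learner_probabilities.stub_learner <- function(learner, sentence) {
  if (is.null(learner$probs)) NULL else learner$probs[[sentence$id]]
}
has_probabilities.stub_learner <- function(learner) !is.null(learner$probs)

# Register stub methods in testthat's environment.
registerS3method("decision_values", "stub_learner", decision_values.stub_learner)
registerS3method("learner_probabilities", "stub_learner",
                 learner_probabilities.stub_learner)
registerS3method("has_probabilities", "stub_learner", has_probabilities.stub_learner)

## Independent oracles -------------------------------------------------------

# Yates continuity-corrected chi-square in its textbook cell-sum form
# sum over cells of (|observed - expected| - 1/2)^2 / expected, algebraically
# distinct from the closed form used by the implementation.
oracle_yates <- function(a, b, c, d) {
  N <- a + b + c + d
  obs <- c(a, b, c, d)
  exp_ <- c((a + b) * (a + c), (a + b) * (b + d),
            (c + d) * (a + c), (c + d) * (b + d)) / N
  sum((abs(obs - exp_) - 0.5)^2 / exp_)
}

oracle_relative_risk <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  risk1 <- a / (a + b); risk2 <- c / (c + d)
  risk1 / risk2
}

oracle_odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  (a / b) / (c / d)
}

# Random synthetic documents (annotations of all three kinds) for round-trip
# property tests; exercised independently of generate_corpus().
random_roundtrip_doc <- function(id, cs, ne_rate = 0.5) {
  ns <- sample(1:4, 1L)
  sentences <- lapply(seq_len(ns), function(k) {
    nt <- sample(3:7, 1L)
    toks <- sample(c("alpha", "beta", "gamma", "delta", "eps"), nt, replace = TRUE)
    n_ann <- sample(0:2, 1L)
    gold <- if (n_ann > 0) sample(cs$id, n_ann, replace = TRUE) else character()
    pas <- if (nt >= 2L) cbind(toks[-nt], "arg", toks[-1L]) else NULL
    make_sentence(toks, gold = gold, ne = rpois(1L, ne_rate),
                  id = paste0(id, ":", k), pas = pas)
  })
  al_document(id, sentences)
}

expect_same_document <- function(d1, d2) {
  expect_identical(d1$id, d2$id)
  expect_equal(document_size(d1), document_size(d2))
  for (k in seq_len(document_size(d1))) {
    s1 <- d1$sentences[[k]]; s2 <- d2$sentences[[k]]
    expect_identical(s1$text, s2$text)
    expect_identical(s1$tokens, s2$tokens)
    expect_identical(sort(s1$gold_concepts), sort(s2$gold_concepts))
    expect_identical(s1$ne_count, s2$ne_count)
    expect_equal(unname(s1$pas_units), unname(s2$pas_units))
  }
}
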