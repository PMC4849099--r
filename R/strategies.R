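#' Rank a document pool by informativity
#'
#' Scores every document with the combined sentence informativity (averaged
#' over sentences) and orders them by descending score, breaking ties by
#' ascending document id.
#'
#' @param documents list of candidate documents (the unlabeled pool).
#' @param concept_set the active [concept_set()].
#' @param config an [informativity_config()].
#' @param learner the base recognizer at the current round.
#' @param prior a [fit_prior()] model.
#' @param ngram_model,pas_model fitted correlation models as needed by
#'   `config`.
#' @param sim optional similarity provider for OOV backoff.
#' @return The documents, reordered; the attribute `"scores"` holds a data
#'   frame `rank, doc_id, score, strategy`.
#' @export
rank_informativity <- function(documents, concept_set, config, learner, prior,
                               ngram_model = NULL, pas_model = NULL,
                               sim = NULL) {
  scorer <- function(s) combined_sentence_informativity(
    s, config, learner, prior, concept_set,
    ngram_model = ngram_model, pas_model = pas_model, sim = sim)
  rank_by_score(documents, function(d) document_informativity(d, scorer),
                "informativity")
}

rank_by_score <- function(documents, doc_scorer, strategy) {
  if (length(documents) == 0L) {
    out <- documents
    attr(out, "scores") <- data.frame(rank = integer(), doc_id = character(),
                                      score = numeric(), strategy = character())
    return(out)
  }
  ids <- doc_ids(documents)
  scores <- vapply(documents, doc_scorer, numeric(1L))
  ord <- order(-scores, ids)
  out <- documents[ord]
  attr(out, "scores") <- data.frame(rank = seq_along(ord), doc_id = ids[ord],
                                    score = scores[ord], strategy = strategy,
                                    stringsAsFactors = FALSE)
  out
}

#' Binary entropy in bits
#'
#' `-p*log2(p) - (1-p)*log2(1-p)`, with `0*log(0) = 0`.
#'
#' @param p probability (vectorized), in `[0, 1]`.
#' @return entropy in bits.
#' @export
binary_entropy <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  term <- function(q) ifelse(q > 0, -q * log2(q), 0)
  term(p) + term(1 - p)
}

# Shared nesting of the uncertainty strategies: sum over sentences of
# (1/len) * sum over in-vocabulary n-gram occurrences of
# sum over concepts of kernel(p(concept-feature probability)).
uncertainty_document_score <- function(document, model, kernel) {
  total <- 0
  for (s in document$sentences) {
    len <- s$word_count
    if (len == 0L) next
    feats <- feature_extractor(model$features)(s)
    idx <- match(feats, model$vocabulary)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0L) next
    P <- exp(model$W[idx, , drop = FALSE] -
               matrix(model$log_norm, length(idx), ncol(model$W), byrow = TRUE))
    total <- total + sum(kernel(P)) / len
  }
  total
}

#' Entropy-based document score
#'
#' Uncertainty baseline: for each sentence, the per-word-normalized sum over
#' its in-vocabulary n-gram occurrences and over all concepts of the binary
#' entropy of the feature-concept probability ([feature_probability()]);
#' summed over sentences. Unknown n-grams contribute nothing.
#'
#' @param document an [al_document()].
#' @param concept_set the active [concept_set()] (must match the model).
#' @param model a fitted n-gram [fit_correlation_model()].
#' @param prior unused; accepted for interface symmetry with the other
#'   strategies.
#' @return non-negative score.
#' @export
entropy_document_score <- function(document, concept_set, model, prior = NULL) {
  stopifnot(all(concept_ids(concept_set) %in% model$concepts))
  uncertainty_document_score(document, model, binary_entropy)
}

#' Gibbs-error document score
#'
#' Same nesting as [entropy_document_score()] with the Gibbs-error kernel
#' `1 - p^2`.
#'
#' @inheritParams entropy_document_score
#' @return non-negative score.
#' @export
gibbs_document_score <- function(document, concept_set, model, prior = NULL) {
  stopifnot(all(concept_ids(concept_set) %in% model$concepts))
  uncertainty_document_score(document, model, function(p) 1 - p^2)
}

#' Committee disagreement of a document
#'
#' Conventional committee selection: the summed absolute difference, over
#' sentences and concepts, between the statistical posterior (computed for
#' every sentence, without recognizer filtering) and the recognizer's own
#' distribution over concepts. The recognizer side uses its probability
#' capability when declared; otherwise the difference-2 confidence of its
#' decision values is pushed through a softmax over concepts.
#'
#' @param document an [al_document()].
#' @param concept_set the active [concept_set()].
#' @param learner base recognizer exposing decision values or probabilities.
#' @param prior a [fit_prior()] model.
#' @param model fitted correlation model.
#' @param sim optional similarity provider.
#' @return non-negative disagreement, at most
#'   `length(concept_set) * document_size(document)` when both sides are
#'   probability-bounded.
#' @export
committee_disagreement <- function(document, concept_set, learner, prior,
                                   model, sim = NULL) {
  cids <- concept_ids(concept_set)
  total <- 0
  for (s in document$sentences) {
    p_inf <- sentence_posteriors(s, prior, model, sim = sim)[cids]
    p_learner <- learner_probabilities(learner, s)
    if (is.null(p_learner)) {
      dv <- decision_values(learner, s)
      conf <- difference2_confidence(dv)
      p_learner <- softmax(setNames(rep(conf, length(cids)), cids))
    }
    total <- total + sum(abs(p_inf - p_learner[cids]))
  }
  total
}

#' Random document ranking
#'
#' A uniform, seed-reproducible permutation of the pool — the reference
#' selection strategy for deficiency.
#'
#' @param documents list of documents.
#' @param seed integer seed.
#' @return documents in permuted order, with a `"scores"` attribute as in
#'   [rank_informativity()] (score = negated rank).
#' @export
random_ranking <- function(documents, seed) {
  if (length(documents) == 0L) return(rank_by_score(documents, identity, "random"))
  perm <- with_preserved_seed(seed, sample.int(length(documents)))
  ids <- doc_ids(documents)
  out <- documents[perm]
  attr(out, "scores") <- data.frame(rank = seq_along(perm), doc_id = ids[perm],
                                    score = -seq_along(perm), strategy = "random",
                                    stringsAsFactors = FALSE)
  out
}

#' Rank a pool with a named strategy
#'
#' Dispatcher used by the selection loop and the command-line tool.
#'
#' @param documents the unlabeled pool.
#' @param strategy one of `"informativity"`, `"committee"`, `"entropy"`,
#'   `"gibbs"`, `"random"`.
#' @param concept_set,config,learner,prior,ngram_model,pas_model,sim scoring
#'   ingredients; which are required depends on the strategy.
#' @param seed seed for `"random"`.
#' @return ordered documents with a `"scores"` attribute.
#' @export
rank_pool <- function(documents, strategy, concept_set = NULL, config = NULL,
                      learner = NULL, prior = NULL, ngram_model = NULL,
                      pas_model = NULL, sim = NULL, seed = 1L) {
  switch(match.arg(strategy, c("informativity", "committee", "entropy",
                               "gibbs", "random")),
         informativity = rank_informativity(documents, concept_set, config,
                                            learner, prior, ngram_model,
                                            pas_model, sim),
         committee = rank_by_score(documents, function(d)
           committee_disagreement(d, concept_set, learner, prior, ngram_model,
                                  sim), "committee"),
         entropy = rank_by_score(documents, function(d)
           entropy_document_score(d, concept_set, ngram_model, prior), "entropy"),
         gibbs = rank_by_score(documents, function(d)
           gibbs_document_score(d, concept_set, ngram_model, prior), "gibbs"),
         random = random_ranking(documents, seed))
}

#' Write a ranking to a tab-separated file
#'
#' Lines `rank<TAB>docid<TAB>score<TAB>strategy`.
#'
#' @param ranked output of [rank_pool()] (documents with a `"scores"`
#'   attribute).
#' @param path file path.
#' @export
write_ranking <- function(ranked, path) {
  sc <- attr(ranked, "scores")
  if (is.null(sc)) stop("no scores attached to the ranking")
  writeLines(sprintf("%d\t%s\t%.17g\t%s", sc$rank, sc$doc_id, sc$score,
                     sc$strategy), path)
  invisible(path)
}
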