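#' Configuration of the informativity estimator
#'
#' Bundles the tunable parameters of the statistical informativity score. The
#' defaults are the tuned operating point reported for the method:
#' participant weight `delta = 0.25`, combination weights
#' `(alpha, beta, gamma) = (0.1, 0.1, 0.8)` for the n-gram, predicate-argument
#' and participant terms, and `k = 25` similar words for out-of-vocabulary
#' backoff.
#'
#' @param delta weight of one participant name mention (>= 0).
#' @param alpha,beta,gamma linear-combination weights (>= 0) of the n-gram,
#'   PAS and participant informativity components.
#' @param k number of nearest in-vocabulary neighbors for OOV backoff (>= 1).
#' @param feature_kind `"ngram"`, `"pas"` or `"combined"`; NER mode allows
#'   n-grams only.
#' @param ngram_order n-gram order(s) for the n-gram component.
#' @param oov_enabled apply OOV backoff to unknown unigrams (needs a
#'   similarity provider at scoring time).
#' @param method correlation measure used when fitting models.
#' @param task `"event"` (events/relations; the concept set may also carry a
#'   participant NE signal) or `"ner"` (entity concept set, n-grams only).
#' @return An object of class `informativity_config`.
#' @export
informativity_config <- function(delta = 0.25, alpha = 0.1, beta = 0.1,
                                 gamma = 0.8, k = 25L,
                                 feature_kind = c("ngram", "pas", "combined"),
                                 ngram_order = 1L, oov_enabled = FALSE,
                                 method = c("chi2_yates", "relative_risk", "odds_ratio"),
                                 task = c("event", "ner")) {
  feature_kind <- match.arg(feature_kind)
  task <- match.arg(task)
  method <- match.arg(method)
  weights <- c(delta, alpha, beta, gamma)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("delta, alpha, beta, gamma must be finite and >= 0")
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (task == "ner" && feature_kind != "ngram")
    stop("NER mode uses n-gram features only")
  structure(list(delta = delta, alpha = alpha, beta = beta, gamma = gamma,
                 k = k, feature_kind = feature_kind,
                 ngram_order = as.integer(ngram_order),
                 oov_enabled = isTRUE(oov_enabled), method = method,
                 task = task),
            class = "informativity_config")
}

#' Maximum-likelihood concept prior
#'
#' `p(concept)` is the fraction of annotated sentence-concept pairs carrying
#' the concept: the count of labeled sentences annotated with it divided by
#' the total over all concepts. Concepts never annotated receive a floor of
#' `1e-6` before renormalization so posteriors stay positive.
#'
#' @param labeled_sentences annotated sentences with at least one annotation
#'   overall.
#' @param concept_set the active [concept_set()].
#' @return An object of class `prior_model`: a named probability vector over
#'   the concept set, summing to 1.
#' @export
fit_prior <- function(labeled_sentences, concept_set) {
  cids <- concept_ids(concept_set)
  counts <- setNames(numeric(length(cids)), cids)
  for (s in labeled_sentences) {
    g <- unique(s$gold_concepts)
    counts[g] <- counts[g] + 1
  }
  if (sum(counts) == 0) stop("no annotations in the labeled pool")
  counts[counts == 0] <- 1e-6
  structure(counts / sum(counts), class = "prior_model")
}

## ---------------------------------------------------------------------------
## Similarity providers (word-vector file or pairwise table)

#' Similarity providers for out-of-vocabulary backoff
#'
#' A similarity provider answers two queries: the similarity of a word pair,
#' and the top-k most similar in-vocabulary words of a given word.
#' `similarity_table()` builds one from a data frame of pairwise similarities
#' (symmetrized; self-similarity is 1); `read_similarity_table()` reads the
#' same from a tab-separated file `w1<TAB>w2<TAB>sim`;
#' `read_word_vectors()` reads the whitespace-separated text vector format
#' (first line `vocab_count dimension`, then `word v1 ... vd`) and uses cosine
#' similarity.
#'
#' @param pairs data frame with columns `w1`, `w2`, `sim` (`sim` in
#'   `[-1, 1]`).
#' @return An object of class `similarity_provider`.
#' @export
similarity_table <- function(pairs) {
  stopifnot(all(c("w1", "w2", "sim") %in% names(pairs)))
  if (nrow(pairs) > 0 && any(abs(pairs$sim) > 1))
    stop("similarities must lie in [-1, 1]")
  sym <- rbind(data.frame(w1 = as.character(pairs$w1), w2 = as.character(pairs$w2),
                          sim = as.numeric(pairs$sim)),
               data.frame(w1 = as.character(pairs$w2), w2 = as.character(pairs$w1),
                          sim = as.numeric(pairs$sim)))
  sym <- unique(sym)
  structure(list(type = "table", pairs = sym), class = "similarity_provider")
}

#' @rdname similarity_table
#' @param path file path.
#' @export
read_similarity_table <- function(path) {
  df <- read.delim(path, header = FALSE, col.names = c("w1", "w2", "sim"),
                   stringsAsFactors = FALSE)
  similarity_table(df)
}

#' @rdname similarity_table
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed word-vector header: ", lines[1L])
  body <- lines[-1L]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  words <- vapply(parts, `[[`, "", 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(mat) <- words
  norms <- sqrt(rowSums(mat^2))
  norms[norms == 0] <- 1
  structure(list(type = "vectors", vectors = mat / norms),
            class = "similarity_provider")
}

#' @rdname similarity_table
#' @param provider a `similarity_provider`.
#' @param w1,w2 words.
#' @export
sim_lookup <- function(provider, w1, w2) {
  stopifnot(inherits(provider, "similarity_provider"))
  if (identical(w1, w2)) return(1)
  if (provider$type == "table") {
    hit <- provider$pairs$sim[provider$pairs$w1 == w1 & provider$pairs$w2 == w2]
    if (length(hit) == 0L) 0 else hit[1L]
  } else {
    v <- provider$vectors
    if (!(w1 %in% rownames(v)) || !(w2 %in% rownames(v))) return(0)
    sum(v[w1, ] * v[w2, ])
  }
}

#' @rdname similarity_table
#' @param word query word.
#' @param k number of neighbors.
#' @param vocabulary candidate neighbor words (the model's training
#'   vocabulary).
#' @export
sim_neighbors <- function(provider, word, k, vocabulary) {
  stopifnot(inherits(provider, "similarity_provider"))
  if (k < 1L) stop("k must be >= 1")
  if (provider$type == "table") {
    sub <- provider$pairs[provider$pairs$w1 == word &
                            provider$pairs$w2 %in% vocabulary, , drop = FALSE]
    if (nrow(sub) == 0L) return(setNames(numeric(), character()))
    sub <- sub[order(-sub$sim, sub$w2), , drop = FALSE]
    sub <- head(sub, k)
    setNames(sub$sim, sub$w2)
  } else {
    v <- provider$vectors
    cand <- intersect(vocabulary, rownames(v))
    if (!(word %in% rownames(v)) || length(cand) == 0L)
      return(setNames(numeric(), character()))
    sims <- as.numeric(v[cand, , drop = FALSE] %*% v[word, ])
    names(sims) <- cand
    sims <- sims[order(-sims, names(sims))]
    head(sims, k)
  }
}

#' Out-of-vocabulary backoff weight
#'
#' For a unigram unseen at fit time, the correlation weight against a concept
#' is reconstructed from its top-k most similar in-vocabulary words:
#' `W_OOV(w, concept) = sum over top-k neighbors of
#' W(neighbor, concept) * Sim(w, neighbor)`. Returns 0 when the provider
#' knows no in-vocabulary neighbor.
#'
#' @param word the unknown unigram.
#' @param concept concept identifier.
#' @param model a fitted [fit_correlation_model()] (n-gram features).
#' @param sim a [similarity_table()]-style provider.
#' @param k number of neighbors (>= 1).
#' @return The backoff weight (same scale as the model's `W`).
#' @export
oov_weight <- function(word, concept, model, sim, k = 25L) {
  w <- oov_weights_all(word, model, sim, k)
  if (!(concept %in% names(w))) stop("unknown concept: ", concept)
  w[[concept]]
}

# Backoff weights for all concepts at once (one neighbor query).
oov_weights_all <- function(word, model, sim, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  nb <- sim_neighbors(sim, word, k, model$vocabulary)
  out <- setNames(numeric(length(model$concepts)), model$concepts)
  if (length(nb) == 0L) return(out)
  Wn <- model$W[names(nb), , drop = FALSE]
  # sequential accumulation keeps the result bit-identical to a plain sum
  setNames(colSums(Wn * nb), model$concepts)
}

## ---------------------------------------------------------------------------
## Sentence-level scores

#' Sentence-concept correlation score Z
#'
#' The average, over the sentence's feature-unit occurrences, of the
#' conditional feature probability given the concept, normalized by the
#' sentence word count: `Z(S, concept) = (1/len(S)) * sum_j p(f_j | concept)`.
#' Occurrences are counted with multiplicity. Features outside the model
#' vocabulary contribute 0, unless they are unigrams and OOV backoff is
#' enabled, in which case their probability is derived from the backoff
#' weight (see Details).
#'
#' For an OOV unigram the raw backoff weight of [oov_weight()] is mapped to a
#' probability by adding the word to the normalizing universe:
#' `p = plogis(W_OOV - logZ_concept)`, which is bounded by 1 and reduces to
#' the in-vocabulary softmax scale.
#'
#' @param sentence an [al_sentence()]; zero-length sentences score 0.
#' @param concept concept identifier.
#' @param model a fitted [fit_correlation_model()].
#' @param sim optional similarity provider for OOV backoff.
#' @param oov_enabled apply OOV backoff to unknown unigrams.
#' @param k OOV neighbor count.
#' @return A single non-negative number.
#' @export
z_score <- function(sentence, concept, model, sim = NULL,
                    oov_enabled = FALSE, k = 25L) {
  z <- z_scores_all(sentence, model, sim = sim, oov_enabled = oov_enabled, k = k)
  if (!(concept %in% names(z))) stop("unknown concept: ", concept)
  z[[concept]]
}

# Z(S, concept) for all model concepts at once.
z_scores_all <- function(sentence, model, sim = NULL, oov_enabled = FALSE,
                         k = 25L) {
  concepts <- model$concepts
  zero <- setNames(numeric(length(concepts)), concepts)
  len <- sentence$word_count
  if (len == 0L) return(zero)
  feats <- feature_extractor(model$features)(sentence)
  if (length(feats) == 0L) return(zero)
  idx <- match(feats, model$vocabulary)
  total <- zero
  known <- which(!is.na(idx))
  if (length(known) > 0L) {
    P <- exp(model$W[idx[known], , drop = FALSE] -
               matrix(model$log_norm, length(known), length(concepts), byrow = TRUE))
    total <- total + colSums(P)
  }
  unknown <- feats[is.na(idx)]
  if (length(unknown) > 0L && oov_enabled && !is.null(sim) &&
      model$features$kind == "ngram") {
    unknown <- unknown[!grepl(" ", unknown, fixed = TRUE)]  # unigrams only
    if (length(unknown) > 0L) {
      tab <- table(unknown)
      for (w in names(tab)) {
        woov <- oov_weights_all(w, model, sim, k)
        total <- total + tab[[w]] * plogis(woov - model$log_norm)
      }
    }
  }
  total / len
}

#' Sentence likelihood over the concept set
#'
#' Softmax across concepts of the Z scores: `p(S | concept) =
#' exp(Z(S, concept)) / sum_j exp(Z(S, concept_j))`, a distribution over the
#' concept set summing to 1.
#'
#' @inheritParams z_score
#' @param concept_set the active [concept_set()] (must be covered by the
#'   model).
#' @return named probability vector over the concept set.
#' @export
sentence_likelihood <- function(sentence, concept_set, model, sim = NULL,
                                oov_enabled = FALSE, k = 25L) {
  cids <- concept_ids(concept_set)
  if (length(cids) < 1L) stop("empty concept set")
  z <- z_scores_all(sentence, model, sim = sim, oov_enabled = oov_enabled, k = k)
  if (!all(cids %in% names(z))) stop("model does not cover the concept set")
  softmax(z[cids])
}

#' Posterior score of a concept in a sentence
#'
#' Bayes product `p(concept) * p(S | concept)` with the sentence marginal
#' treated as the constant 1, so scores are comparable across sentences (full
#' normalization would make every sentence's posteriors sum to one and erase
#' the ranking signal).
#'
#' @inheritParams sentence_likelihood
#' @param concept concept identifier.
#' @param prior a [fit_prior()] model.
#' @return value in `[0, 1]`.
#' @export
concept_posterior <- function(sentence, concept, prior, model, sim = NULL,
                              oov_enabled = FALSE, k = 25L) {
  p <- sentence_posteriors(sentence, prior, model, sim = sim,
                           oov_enabled = oov_enabled, k = k)
  if (!(concept %in% names(p))) stop("unknown concept: ", concept)
  p[[concept]]
}

sentence_posteriors <- function(sentence, prior, model, sim = NULL,
                                oov_enabled = FALSE, k = 25L) {
  stopifnot(inherits(prior, "prior_model"))
  cids <- names(prior)
  z <- z_scores_all(sentence, model, sim = sim, oov_enabled = oov_enabled, k = k)
  if (!all(cids %in% names(z))) stop("model does not cover the prior's concepts")
  lik <- softmax(z[cids])
  unclass(prior) * lik
}

#' Filtered sentence informativity
#'
#' The core committee step: concepts the base recognizer already extracts
#' from the sentence contribute nothing; every other concept contributes its
#' posterior score. The sum over the concept set is the sentence's
#' informativity.
#'
#' @inheritParams concept_posterior
#' @param concept_set the active [concept_set()].
#' @param learner the base recognizer (see [mock_train()]), trained for the
#'   current round.
#' @return non-negative informativity score.
#' @export
sentence_informativity <- function(sentence, concept_set, learner, prior,
                                   model, sim = NULL, oov_enabled = FALSE,
                                   k = 25L) {
  post <- sentence_posteriors(sentence, prior, model, sim = sim,
                              oov_enabled = oov_enabled, k = k)
  cids <- concept_ids(concept_set)
  rec <- recognized_concepts(learner, sentence)
  sum(post[cids][!(cids %in% rec)])
}

#' Participant-based informativity
#'
#' `delta * T`, where `T` is the number of participant (gene/protein) name
#' mentions predicted in the sentence — evidence that an event may be present
#' even when no trigger vocabulary is recognized. `T` comes from the
#' recognizer when one is supplied, else from the sentence's stored count.
#'
#' @param sentence an [al_sentence()].
#' @param delta participant weight (>= 0); 0.25 is the tuned default.
#' @param learner optional recognizer exposing a participant count.
#' @return `delta * T`.
#' @export
ne_informativity <- function(sentence, delta = 0.25, learner = NULL) {
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0")
  T_ <- if (is.null(learner)) sentence$ne_count else learner_ne_count(learner, sentence)
  delta * T_
}

#' Linearly combined sentence informativity
#'
#' `alpha * I_ngram + beta * I_pas + gamma * (delta * T)`: the weighted sum of
#' the n-gram informativity (with OOV backoff if enabled), the
#' predicate-argument informativity, and the participant term. The additive
#' n-gram + participant form is the special case `(alpha, gamma) = (1, 1)`,
#' `beta = 0`. In NER mode the score is the n-gram informativity alone, over
#' the entity concept set.
#'
#' @param sentence an [al_sentence()].
#' @param config an [informativity_config()].
#' @param learner base recognizer for the current round.
#' @param prior a [fit_prior()] model.
#' @param ngram_model,pas_model fitted correlation models for the feature
#'   kinds with nonzero weight (`NULL` otherwise).
#' @param concept_set the active [concept_set()].
#' @param sim optional similarity provider.
#' @return non-negative combined score.
#' @export
combined_sentence_informativity <- function(sentence, config, learner, prior,
                                            concept_set, ngram_model = NULL,
                                            pas_model = NULL, sim = NULL) {
  stopifnot(inherits(config, "informativity_config"))
  if (config$task == "ner") {
    if (is.null(ngram_model)) stop("NER mode needs a fitted n-gram model")
    return(sentence_informativity(sentence, concept_set, learner, prior,
                                  ngram_model, sim = sim,
                                  oov_enabled = config$oov_enabled,
                                  k = config$k))
  }
  total <- 0
  if (config$alpha > 0) {
    if (is.null(ngram_model)) stop("alpha > 0 needs a fitted n-gram model")
    total <- total + config$alpha *
      sentence_informativity(sentence, concept_set, learner, prior,
                             ngram_model, sim = sim,
                             oov_enabled = config$oov_enabled, k = config$k)
  }
  if (config$beta > 0) {
    if (is.null(pas_model)) stop("beta > 0 needs a fitted PAS model")
    total <- total + config$beta *
      sentence_informativity(sentence, concept_set, learner, prior, pas_model)
  }
  if (config$gamma > 0) {
    total <- total + config$gamma *
      ne_informativity(sentence, config$delta, learner)
  }
  total
}

#' Document informativity
#'
#' The mean of a sentence-level score over a document's sentences — the
#' quantity the selection strategies rank.
#'
#' @param document an [al_document()] with at least one sentence.
#' @param scorer function mapping a sentence to its score.
#' @return mean sentence score.
#' @export
document_informativity <- function(document, scorer) {
  if (document_size(document) < 1L) stop("cannot score an empty document")
  mean(vapply(document$sentences, scorer, numeric(1L)))
}
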