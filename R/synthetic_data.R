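#' Specification of a synthetic annotated corpus
#'
#' Describes a corpus with the statistical structure the informativity
#' estimator assumes: an ontology of concepts, each with a small disjoint
#' trigger vocabulary planted into otherwise noisy sentences; participant
#' name mentions occurring at a higher rate in annotated sentences;
#' adjacent-token predicate-argument units; and a dev/train/test document
#' split. The defaults describe a corpus of 200 abstract-sized documents over
#' a 10-concept ontology with 5 trigger keywords per concept against a
#' 500-word background vocabulary.
#'
#' @param n_concepts number of ontology concepts.
#' @param keywords_per_concept planted trigger keywords per concept.
#' @param background_vocab_size size of the background (noise) vocabulary.
#' @param n_documents total documents across the three splits.
#' @param sentences_per_document inclusive integer range, e.g. `c(3, 8)`.
#' @param tokens_per_sentence inclusive integer range of background tokens.
#' @param concept_prob probability a sentence is annotated with a concept.
#' @param concept_weights relative frequencies of the concepts when a
#'   sentence draws one: `"uniform"` (default — keeps every concept above the
#'   mock recognizer's learnability threshold at this corpus scale),
#'   `"zipf"` (weight `1/rank`, emulating the heavy skew of real ontological
#'   annotation frequencies), or a positive numeric vector of length
#'   `n_concepts`.
#' @param second_concept_prob probability an annotated sentence carries a
#'   second, distinct concept (multi-event sentences).
#' @param emission_prob probability an annotated sentence emits a planted
#'   keyword of each of its concepts.
#' @param ne_rate_concept,ne_rate_background Poisson mean of participant name
#'   mentions in annotated vs. unannotated sentences.
#' @param oov_holdout_fraction fraction of each concept's keywords emitted
#'   only in the test split (out-of-vocabulary at training time); 0 disables
#'   the holdout.
#' @param concept_kind kind of the generated concepts (`"event"` for the
#'   event-extraction setting, `"entity"` for the NER setting,
#'   `"relation"`).
#' @param split named fractions `dev`, `train`, `test` summing to 1.
#' @param seed mandatory integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_concepts = 10L, keywords_per_concept = 5L,
                       background_vocab_size = 500L, n_documents = 200L,
                       sentences_per_document = c(3L, 8L),
                       tokens_per_sentence = c(6L, 12L),
                       concept_prob = 0.4, concept_weights = "uniform",
                       second_concept_prob = 0.15,
                       emission_prob = 0.9, ne_rate_concept = 1.5,
                       ne_rate_background = 0.2,
                       oov_holdout_fraction = 0,
                       concept_kind = "event",
                       split = c(dev = 0.15, train = 0.70, test = 0.15),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  sizes <- c(n_concepts, keywords_per_concept, background_vocab_size,
             n_documents, sentences_per_document, tokens_per_sentence)
  if (any(sizes < 1L)) stop("sizes must be >= 1")
  probs <- c(concept_prob, second_concept_prob, emission_prob,
             oov_holdout_fraction)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must lie in [0, 1]")
  if (oov_holdout_fraction >= 1) stop("oov_holdout_fraction must be < 1")
  if (ne_rate_concept < 0 || ne_rate_background < 0) stop("ne rates must be >= 0")
  if (is.character(concept_weights)) {
    concept_weights <- match.arg(concept_weights, c("uniform", "zipf"))
    concept_weights <- switch(concept_weights,
                              zipf = 1 / seq_len(n_concepts),
                              uniform = rep(1, n_concepts))
  }
  concept_weights <- as.numeric(concept_weights)
  if (length(concept_weights) != n_concepts || any(concept_weights <= 0))
    stop("concept_weights must be ", n_concepts, " positive weights")
  if (abs(sum(split) - 1) > 1e-8 ||
      !all(c("dev", "train", "test") %in% names(split)))
    stop("split must name dev/train/test fractions summing to 1")
  structure(list(n_concepts = as.integer(n_concepts),
                 keywords_per_concept = as.integer(keywords_per_concept),
                 background_vocab_size = as.integer(background_vocab_size),
                 n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 tokens_per_sentence = as.integer(tokens_per_sentence),
                 concept_prob = concept_prob,
                 concept_weights = concept_weights / sum(concept_weights),
                 second_concept_prob = second_concept_prob,
                 emission_prob = emission_prob,
                 ne_rate_concept = ne_rate_concept,
                 ne_rate_background = ne_rate_background,
                 oov_holdout_fraction = oov_holdout_fraction,
                 concept_kind = concept_kind,
                 split = split, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic annotated corpus
#'
#' Draws a corpus per the spec: each sentence is annotated with zero, one or
#' two concepts; annotated sentences emit planted trigger keywords with the
#' spec's emission probability on top of background tokens; participant name
#' mentions are planted at a concept-conditional Poisson rate;
#' predicate-argument units are derived as adjacent-token `(t_i, "arg",
#' t_{i+1})` pairs. When a holdout fraction is set, held-out keywords are
#' emitted only in test-split documents, so they are out-of-vocabulary for
#' models fitted on dev/train. Output is byte-deterministic given the seed.
#'
#' @param spec a [synth_spec()].
#' @param dir optional directory; when given, the three splits are written as
#'   standoff corpora under `dir/dev`, `dir/train`, `dir/test` plus the
#'   ground-truth `keywords.tsv` (`concept<TAB>keyword<TAB>held_out`).
#' @return list with elements `dev`, `train`, `test` (document lists),
#'   `concept_set`, `keywords` (data frame `concept`, `keyword`, `held_out`
#'   — the oracle for recovery checks), and `spec`.
#' @export
generate_corpus <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_preserved_seed(spec$seed, generate_corpus_impl(spec, dir))
}

generate_corpus_impl <- function(spec, dir) {
  prefix <- if (spec$concept_kind == "entity") "N" else "E"
  concepts <- sprintf("%s%02d", prefix, seq_len(spec$n_concepts))
  cs <- concept_set(concepts, kind = spec$concept_kind)
  keywords <- do.call(rbind, lapply(concepts, function(cc) {
    data.frame(concept = cc,
               keyword = sprintf("%skw%02d", tolower(cc),
                                 seq_len(spec$keywords_per_concept)),
               stringsAsFactors = FALSE)
  }))
  keywords$held_out <- FALSE
  if (spec$oov_holdout_fraction > 0) {
    for (cc in concepts) {
      idx <- which(keywords$concept == cc)
      n_hold <- floor(spec$oov_holdout_fraction * length(idx))
      if (n_hold >= length(idx))
        stop("holdout would leave a concept with no training keywords")
      if (n_hold > 0L)
        keywords$held_out[sample(idx, n_hold)] <- TRUE
    }
  }
  background <- sprintf("w%04d", seq_len(spec$background_vocab_size))
  # gene/protein names are an open class: a wide lexicon keeps any single
  # name from accumulating concept co-occurrence counts
  ne_lexicon <- sprintf("gprot%03d", 1:200)

  n <- spec$n_documents
  n_dev <- max(1L, round(spec$split[["dev"]] * n))
  n_test <- max(1L, round(spec$split[["test"]] * n))
  n_train <- n - n_dev - n_test
  split_of <- rep(c("dev", "train", "test"), c(n_dev, n_train, n_test))

  docs <- vector("list", n)
  for (d in seq_len(n)) {
    docid <- sprintf("d%04d", d)
    in_test <- split_of[d] == "test"
    ns <- sample(spec$sentences_per_document[1L]:spec$sentences_per_document[2L], 1L)
    sentences <- vector("list", ns)
    for (k in seq_len(ns)) {
      anns <- character()
      if (runif(1) < spec$concept_prob) {
        anns <- sample(concepts, 1L, prob = spec$concept_weights)
        if (runif(1) < spec$second_concept_prob) {
          rest <- setdiff(concepts, anns)
          anns <- c(anns, sample(rest, 1L,
                                 prob = spec$concept_weights[match(rest, concepts)]))
        }
      }
      nt <- sample(spec$tokens_per_sentence[1L]:spec$tokens_per_sentence[2L], 1L)
      toks <- sample(background, nt, replace = TRUE)
      # distinct slots per concept so one keyword never overwrites another
      slots <- sample(nt, min(nt, length(anns)))
      for (j in seq_along(anns)) {
        if (j <= length(slots) && runif(1) < spec$emission_prob) {
          pool <- keywords$keyword[keywords$concept == anns[j] &
                                     (in_test | !keywords$held_out)]
          toks[slots[j]] <- sample(pool, 1L)
        }
      }
      rate <- if (length(anns) > 0L) spec$ne_rate_concept else spec$ne_rate_background
      T_ <- rpois(1L, rate)
      if (T_ > 0L)
        toks <- append(toks, sample(ne_lexicon, T_, replace = TRUE),
                       after = sample(length(toks), 1L))
      text <- paste(toks, collapse = " ")
      pas <- if (length(toks) >= 2L) {
        cbind(toks[-length(toks)], "arg", toks[-1L])
      } else matrix(character(), 0L, 3L)
      sentences[[k]] <- al_sentence(id = paste0(docid, ":", k), text = text,
                                    gold_concepts = anns, pas_units = pas,
                                    ne_count = T_)
    }
    docs[[d]] <- al_document(docid, sentences)
  }
  out <- list(dev = docs[split_of == "dev"], train = docs[split_of == "train"],
              test = docs[split_of == "test"], concept_set = cs,
              keywords = keywords, spec = spec)
  if (!is.null(dir)) {
    for (sp in c("dev", "train", "test"))
      write_standoff_corpus(out[[sp]], file.path(dir, sp), cs)
    write.table(keywords, file.path(dir, "keywords.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  out
}

#' Build a synthetic similarity provider for OOV experiments
#'
#' Pairs every held-out keyword with the retained keywords: high similarity
#' (uniform in `[0.85, 0.95]`) to retained keywords of the same concept, low
#' (uniform in `[0, 0.1]`) to retained keywords of other concepts — the
#' structure a word-embedding neighborhood would supply for a true trigger
#' synonym.
#'
#' @param keywords keyword map from [generate_corpus()] (columns `concept`,
#'   `keyword`, and optionally `held_out`).
#' @param holdout when the map has no holdout marks yet, the fraction of each
#'   concept's keywords to hold out here.
#' @param seed integer seed.
#' @return list with `provider` (a [similarity_table()]) and `held_out` (data
#'   frame `concept`, `word`).
#' @export
generate_similarity_provider <- function(keywords, holdout = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  with_preserved_seed(seed, {
    if (is.null(keywords$held_out)) keywords$held_out <- FALSE
    if (!any(keywords$held_out) && !is.null(holdout) && holdout > 0) {
      if (holdout >= 1) stop("holdout must be < 1")
      for (cc in unique(keywords$concept)) {
        idx <- which(keywords$concept == cc)
        n_hold <- floor(holdout * length(idx))
        if (n_hold >= length(idx))
          stop("holdout would leave a concept with no training keywords")
        if (n_hold > 0L) keywords$held_out[sample(idx, n_hold)] <- TRUE
      }
    }
    held <- keywords[keywords$held_out, , drop = FALSE]
    kept <- keywords[!keywords$held_out, , drop = FALSE]
    pairs <- data.frame(w1 = character(), w2 = character(), sim = numeric())
    if (nrow(held) > 0L) {
      grid <- expand.grid(h = seq_len(nrow(held)), r = seq_len(nrow(kept)))
      same <- held$concept[grid$h] == kept$concept[grid$r]
      pairs <- data.frame(w1 = held$keyword[grid$h], w2 = kept$keyword[grid$r],
                          sim = ifelse(same, runif(nrow(grid), 0.85, 0.95),
                                       runif(nrow(grid), 0, 0.1)),
                          stringsAsFactors = FALSE)
    }
    list(provider = similarity_table(pairs),
         held_out = data.frame(concept = held$concept, word = held$keyword,
                               stringsAsFactors = FALSE))
  })
}
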