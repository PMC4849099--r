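#' The base-recognizer contract
#'
#' The active-learning loop treats the underlying extraction system (an SVM
#' event extractor, a CRF entity tagger, ...) as an opaque recognizer behind
#' four S3 generics. An adapter for a real system must provide:
#'
#' * `decision_values(learner, sentence)`: a named real vector over concepts;
#'   a value `>= 0` means the concept is recognized in the sentence (the sign
#'   convention the default [recognizes()] relies on).
#' * `recognizes(learner, sentence, concept)`: logical; default derives from
#'   `decision_values`.
#' * `learner_probabilities(learner, sentence)`: a probability distribution
#'   over concepts, or `NULL` when the system has no probability capability
#'   (then committee disagreement falls back to the difference-2 confidence);
#'   [has_probabilities()] declares the capability.
#' * `learner_ne_count(learner, sentence)`: predicted participant name
#'   mentions (`T` of the participant term).
#'
#' @param learner a recognizer object.
#' @param sentence an [al_sentence()].
#' @param concept concept identifier.
#' @name recognizer-contract
NULL

#' @rdname recognizer-contract
#' @export
decision_values <- function(learner, sentence) UseMethod("decision_values")

#' @export
decision_values.default <- function(learner, sentence)
  stop("recognizer contract violation: no decision_values method for class ",
       paste(class(learner), collapse = "/"))

#' @rdname recognizer-contract
#' @export
recognizes <- function(learner, sentence, concept) UseMethod("recognizes")

#' @export
recognizes.default <- function(learner, sentence, concept) {
  dv <- decision_values(learner, sentence)
  if (!(concept %in% names(dv))) return(FALSE)
  dv[[concept]] >= 0
}

# All concepts the learner recognizes in a sentence (names of dv >= 0).
recognized_concepts <- function(learner, sentence) {
  dv <- decision_values(learner, sentence)
  names(dv)[dv >= 0]
}

#' @rdname recognizer-contract
#' @export
learner_probabilities <- function(learner, sentence) UseMethod("learner_probabilities")

#' @export
learner_probabilities.default <- function(learner, sentence) NULL

#' @rdname recognizer-contract
#' @export
has_probabilities <- function(learner) UseMethod("has_probabilities")

#' @export
has_probabilities.default <- function(learner) FALSE

#' @rdname recognizer-contract
#' @export
learner_ne_count <- function(learner, sentence) UseMethod("learner_ne_count")

#' @export
learner_ne_count.default <- function(learner, sentence) sentence$ne_count

#' Train the mock keyword recognizer
#'
#' A deterministic stand-in for an external extraction system, sufficient to
#' drive closed-loop simulations: it counts, over the labeled pool, how many
#' sentences contain each token while being annotated with each concept. It
#' recognizes a concept in a new sentence iff some token of the sentence has a
#' co-annotation count of at least `threshold`; its decision value for a
#' concept is (max co-count over the sentence's tokens) - threshold. More
#' labeled data can only add recognitions, so recognition is monotone in the
#' pool.
#'
#' @param labeled_documents list of annotated documents.
#' @param threshold minimum co-annotation count (>= 1).
#' @param concept_set optional [concept_set()] fixing the concept universe;
#'   defaults to the concepts observed in training.
#' @return An object of class `mock_keyword_learner`.
#' @export
mock_train <- function(labeled_documents, threshold = 5L, concept_set = NULL) {
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) stop("threshold must be >= 1")
  sentences <- all_sentences(labeled_documents)
  cids <- if (is.null(concept_set)) {
    sort(unique(unlist(lapply(sentences, function(s) s$gold_concepts))))
  } else concept_ids(concept_set)
  if (length(sentences) == 0L || length(cids) == 0L) {
    counts <- matrix(0, 0L, length(cids), dimnames = list(character(), cids))
  } else {
    tm <- presence_matrix(lapply(sentences, function(s) s$tokens))
    cm <- presence_matrix(lapply(sentences, function(s) s$gold_concepts),
                          universe = cids)
    counts <- as.matrix(tm %*% Matrix::t(cm))
  }
  structure(list(counts = counts, threshold = threshold, concepts = cids),
            class = "mock_keyword_learner")
}

#' @export
decision_values.mock_keyword_learner <- function(learner, sentence) {
  idx <- match(unique(sentence$tokens), rownames(learner$counts))
  idx <- idx[!is.na(idx)]
  best <- if (length(idx) == 0L) {
    numeric(length(learner$concepts))
  } else if (length(idx) == 1L) {
    learner$counts[idx, ]
  } else {
    apply(learner$counts[idx, , drop = FALSE], 2L, max)
  }
  setNames(as.numeric(best) - learner$threshold, learner$concepts)
}

#' @export
learner_ne_count.mock_keyword_learner <- function(learner, sentence) sentence$ne_count

#' Serialize the mock learner
#'
#' One `concept<TAB>token<TAB>count` line per nonzero co-annotation count.
#'
#' @param learner a [mock_train()] model.
#' @param path file path.
#' @export
write_mock_learner <- function(learner, path) {
  stopifnot(inherits(learner, "mock_keyword_learner"))
  idx <- which(learner$counts > 0, arr.ind = TRUE)
  lines <- sprintf("%s\t%s\t%d",
                   colnames(learner$counts)[idx[, 2L]],
                   rownames(learner$counts)[idx[, 1L]],
                   as.integer(learner$counts[idx]))
  writeLines(c(paste0("#threshold\t", learner$threshold), lines), path)
  invisible(path)
}

#' Difference-2 confidence
#'
#' The margin heuristic of committee selection with margin classifiers: the
#' decision value of the top-scoring label minus that of the runner-up. With
#' a single label the value is returned unchanged. The result is shared by
#' all concepts of the sentence (the formula does not depend on which concept
#' is asked about).
#'
#' @param values named real vector of per-concept decision values (nonempty).
#' @param target_concept ignored; kept so callers can be explicit about the
#'   concept under consideration.
#' @return the confidence margin.
#' @examples
#' difference2_confidence(c(E1 = 2, E2 = 0.5, E3 = -1))  # 1.5
#' @export
difference2_confidence <- function(values, target_concept = NULL) {
  if (length(values) < 1L) stop("difference2_confidence needs at least one value")
  if (length(values) == 1L) return(unname(values[[1L]]))
  s <- sort(as.numeric(values), decreasing = TRUE)
  s[1L] - s[2L]
}

#' Sentence-level recognition micro-F1
#'
#' Evaluates a recognizer on annotated documents: per sentence, the predicted
#' concept set (all concepts the recognizer fires on) is compared with the
#' unique gold concepts; true/false positives and false negatives are pooled
#' over all sentences (micro-averaging). An evaluation with no gold and no
#' predicted concepts anywhere scores 1.
#'
#' @param learner a recognizer honoring the contract.
#' @param documents annotated evaluation documents.
#' @param concept_set the active [concept_set()].
#' @return micro-F1 in `[0, 1]`.
#' @export
evaluate_recognizer <- function(learner, documents, concept_set) {
  cids <- concept_ids(concept_set)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (s in all_sentences(documents)) {
    pred <- intersect(recognized_concepts(learner, s), cids)
    gold <- intersect(unique(s$gold_concepts), cids)
    tp <- tp + length(intersect(pred, gold))
    fp <- fp + length(setdiff(pred, gold))
    fn <- fn + length(setdiff(gold, pred))
  }
  if (2L * tp + fp + fn == 0L) return(1)
  2 * tp / (2 * tp + fp + fn)
}
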