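#' Learning curve container
#'
#' Per-round scores of the base recognizer on the fixed test split.
#'
#' @param score numeric vector of per-round scores (round 1..n).
#' @param strategy strategy tag.
#' @param n_labeled labeled-pool size after each round (optional).
#' @return An object of class `learning_curve` (a data frame with columns
#'   `round`, `n_labeled`, `score` and a `"strategy"` attribute).
#' @export
learning_curve <- function(score, strategy = "", n_labeled = NA_integer_) {
  if (any(!is.finite(score))) stop("curve scores must be finite")
  out <- data.frame(round = seq_along(score),
                    n_labeled = rep_len(as.integer(n_labeled), length(score)),
                    score = as.numeric(score))
  attr(out, "strategy") <- strategy
  class(out) <- c("learning_curve", "data.frame")
  out
}

curve_scores <- function(curve) {
  if (inherits(curve, "learning_curve") || is.data.frame(curve)) curve$score
  else as.numeric(curve)
}

#' Deficiency of an active-learning curve against a reference
#'
#' Summarizes two learning curves of equal length `n` into a single ratio:
#' `sum_t (acc_n(REF) - acc_t(AL)) / sum_t (acc_n(REF) - acc_t(REF))`. A value
#' below 1 means the active-learning strategy reached the reference's final
#' performance faster than the reference (typically random selection) did;
#' smaller is better. The measure depends only on differences against the
#' reference's final score, so it is invariant to shifting both curves by a
#' constant or rescaling both by a positive factor.
#'
#' @param al,ref [learning_curve()] objects (or plain numeric vectors) of
#'   equal length `n >= 2`.
#' @return the deficiency ratio.
#' @examples
#' deficiency(c(0.75, 1), c(0.5, 1))  # 0.5
#' @export
deficiency <- function(al, ref) {
  a <- curve_scores(al); r <- curve_scores(ref)
  if (length(a) != length(r)) stop("curves must have the same number of rounds")
  n <- length(r)
  if (n < 2L) stop("deficiency needs at least two rounds")
  den <- sum(r[n] - r)
  if (den == 0) stop("degenerate (flat) reference curve: zero denominator")
  sum(r[n] - a) / den
}

#' Sentence-level top-N concept-prediction accuracy
#'
#' The parameter-optimization measure: for each sentence with `N_i >= 1` gold
#' concepts, the `N_i` concepts with the highest posterior score (ties broken
#' by concept identifier) are predicted and the overlap fraction
#' `|top-N_i predicted intersect gold| / N_i` recorded; the mean over
#' sentences is returned. Sentences without gold concepts are skipped (with a
#' message when any are).
#'
#' @param sentences annotated sentences to evaluate on.
#' @param model fitted correlation model.
#' @param prior a [fit_prior()] model.
#' @return accuracy in `[0, 1]`.
#' @export
concept_prediction_accuracy <- function(sentences, model, prior) {
  acc <- numeric(); skipped <- 0L
  for (s in sentences) {
    gold <- unique(s$gold_concepts)
    if (length(gold) == 0L) { skipped <- skipped + 1L; next }
    post <- sentence_posteriors(s, prior, model)
    ord <- names(post)[order(-post, names(post))]
    pred <- ord[seq_len(min(length(gold), length(ord)))]
    acc <- c(acc, length(intersect(pred, gold)) / length(gold))
  }
  if (skipped > 0L)
    message(skipped, " sentence(s) without gold concepts skipped")
  if (length(acc) == 0L) stop("no sentence with gold concepts to evaluate")
  mean(acc)
}

#' Learning-curve CSV round trip
#'
#' CSV with header `round,n_labeled,score`.
#'
#' @param curve a [learning_curve()].
#' @param path file path.
#' @return `read_curve()` returns the reloaded `learning_curve`.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "learning_curve"))
  write.table(as.data.frame(curve)[, c("round", "n_labeled", "score")], path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  df <- read.delim(path, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("round", "n_labeled", "score") %in% names(df)))
    stop("malformed curve file: ", path)
  if (nrow(df) == 0L) stop("empty curve file: ", path)
  learning_curve(df$score, n_labeled = df$n_labeled)
}
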