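#' Sentence-level 2x2 contingency table
#'
#' Cross-classifies the sentences of a labeled pool by whether they contain a
#' feature unit (an n-gram or predicate-argument triple) and whether they
#' express a concept: `a` sentences have both, `b` the feature only, `c` the
#' concept only, `d` neither. Presence is binary — a sentence counts once no
#' matter how often the feature occurs or the concept is annotated.
#'
#' @param a,b,c,d non-negative sentence counts.
#' @return An object of class `contingency_table` with the four cells and the
#'   derived marginals `N_A = a+b`, `N_B = c+d`, `N_S = a+c`, `N_F = b+d`,
#'   `N = a+b+c+d`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- as.numeric(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0)) stop("cell counts must be >= 0")
  structure(list(a = cells[1L], b = cells[2L], c = cells[3L], d = cells[4L],
                 N_A = cells[1L] + cells[2L], N_B = cells[3L] + cells[4L],
                 N_S = cells[1L] + cells[3L], N_F = cells[2L] + cells[4L],
                 N = sum(cells)),
            class = "contingency_table")
}

#' Build feature-concept contingency tables from labeled sentences
#'
#' For every feature unit seen in the sentences and every concept, the four
#' cells partition the sentence list by feature presence and concept
#' expression.
#'
#' @param labeled_sentences list of [al_sentence()] objects carrying gold
#'   concept annotations.
#' @param concept_set the active [concept_set()].
#' @param features a [feature_spec()].
#' @return An object of class `contingency_map`. Use [get_table()] to extract
#'   the table of one (feature, concept) pair, or `as.data.frame()` for all
#'   pairs with `a > 0`.
#' @export
build_tables <- function(labeled_sentences, concept_set,
                         features = feature_spec("ngram", 1L)) {
  extractor <- feature_extractor(features)
  n <- length(labeled_sentences)
  cids <- concept_ids(concept_set)
  if (n == 0L) {
    return(structure(list(joint = matrix(0, 0L, length(cids),
                                         dimnames = list(character(), cids)),
                          n_feat = numeric(), n_concept = setNames(numeric(length(cids)), cids),
                          n = 0L, features = features),
                     class = "contingency_map"))
  }
  fm <- presence_matrix(lapply(labeled_sentences, extractor))
  cm <- presence_matrix(lapply(labeled_sentences, function(s) s$gold_concepts),
                        universe = cids)
  joint <- as.matrix(fm %*% Matrix::t(cm))   # features x concepts
  structure(list(joint = joint,
                 n_feat = setNames(Matrix::rowSums(fm), rownames(fm)),
                 n_concept = setNames(Matrix::rowSums(cm), rownames(cm)),
                 n = n, features = features),
            class = "contingency_map")
}

# Binary items x sentences incidence matrix (presence, not multiplicity).
presence_matrix <- function(item_lists, universe = NULL) {
  uniq <- lapply(item_lists, unique)
  vals <- unlist(uniq, use.names = FALSE)
  if (is.null(universe)) universe <- sort(unique(vals))
  j <- rep.int(seq_along(uniq), lengths(uniq))
  keep <- vals %in% universe
  Matrix::sparseMatrix(i = match(vals[keep], universe), j = j[keep], x = 1,
                       dims = c(length(universe), length(item_lists)),
                       dimnames = list(universe, NULL))
}

#' @rdname build_tables
#' @param map a `contingency_map`.
#' @param feature,concept the pair whose table to extract.
#' @export
get_table <- function(map, feature, concept) {
  stopifnot(inherits(map, "contingency_map"))
  if (!(concept %in% names(map$n_concept))) stop("unknown concept: ", concept)
  fi <- match(feature, rownames(map$joint))
  a <- if (is.na(fi)) 0 else map$joint[fi, concept]
  nf <- if (is.na(fi)) 0 else map$n_feat[[feature]]
  nc <- map$n_concept[[concept]]
  contingency_table(a, nf - a, nc - a, map$n - nf - nc + a)
}

#' @export
as.data.frame.contingency_map <- function(x, ...) {
  idx <- which(x$joint > 0, arr.ind = TRUE)
  if (length(idx) == 0L)
    return(data.frame(feature = character(), concept = character(),
                      a = numeric(), b = numeric(), c = numeric(), d = numeric()))
  feature <- rownames(x$joint)[idx[, 1L]]
  concept <- colnames(x$joint)[idx[, 2L]]
  a <- x$joint[idx]
  data.frame(feature = feature, concept = concept, a = a,
             b = x$n_feat[feature] - a,
             c = x$n_concept[concept] - a,
             d = x$n - x$n_feat[feature] - x$n_concept[concept] + a,
             row.names = NULL)
}

#' Correlation measures on a 2x2 table
#'
#' The three feature-concept association weights used by the informativity
#' estimator. `yates_chi_square()` is the continuity-corrected chi-square
#' statistic, computed as printed in its source form
#' `N * (|ad - bc| - N/2)^2 / (N_S * N_F * N_A * N_B)`; by default the term
#' `(|ad - bc| - N/2)` is squared even when `|ad - bc| < N/2` (set
#' `clamp = TRUE` for the textbook variant that clamps it at zero).
#' `relative_risk()` returns `(a/(a+b)) / (c/(c+d))` and `odds_ratio()`
#' `(a*d)/(b*c)`; both apply the Haldane-Anscombe continuity constant
#' `h = 0.5` to all four cells only when some cell is zero.
#'
#' @param t a [contingency_table()].
#' @param clamp clamp `|ad - bc| - N/2` at zero before squaring.
#' @return The correlation weight, a single number.
#' @examples
#' yates_chi_square(contingency_table(5, 5, 5, 5))   # 0.2
#' yates_chi_square(contingency_table(10, 0, 0, 10)) # 16.2
#' @export
yates_chi_square <- function(t, clamp = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$N_S <= 0 || t$N_F <= 0 || t$N_A <= 0 || t$N_B <= 0)
    stop("degenerate table: zero marginal")
  w_yates(t$a, t$b, t$c, t$d, clamp = clamp)
}

#' @rdname yates_chi_square
#' @export
relative_risk <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$N == 0) stop("degenerate table: all cells zero")
  w_relative_risk(t$a, t$b, t$c, t$d)
}

#' @rdname yates_chi_square
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$N == 0) stop("degenerate table: all cells zero")
  w_odds_ratio(t$a, t$b, t$c, t$d)
}

# Vectorized weight kernels (used for whole-vocabulary fits). Zero marginals
# yield weight 0 in the chi-square fit: such a pair carries no association
# signal either way.
w_yates <- function(a, b, c, d, clamp = FALSE) {
  N <- a + b + c + d
  NA_ <- a + b; NB <- c + d; NS <- a + c; NF <- b + d
  term <- abs(a * d - b * c) - N / 2
  if (clamp) term <- pmax(term, 0)
  den <- NS * NF * NA_ * NB
  out <- ifelse(den > 0, N * term^2 / den, 0)
  out
}

w_relative_risk <- function(a, b, c, d) {
  h <- ifelse(a == 0 | b == 0 | c == 0 | d == 0, 0.5, 0)
  ((a + h) / (a + b + 2 * h)) / ((c + h) / (c + d + 2 * h))
}

w_odds_ratio <- function(a, b, c, d) {
  h <- ifelse(a == 0 | b == 0 | c == 0 | d == 0, 0.5, 0)
  ((a + h) * (d + h)) / ((b + h) * (c + h))
}

#' Shift-invariant softmax
#'
#' Converts a vector of real-valued scores into probabilities
#' `exp(x_i) / sum(exp(x_j))`, computed stably by subtracting the maximum.
#'
#' @param scores named (or unnamed) numeric vector with at least one finite
#'   element.
#' @return probabilities of the same length and names, summing to 1.
#' @export
softmax <- function(scores) {
  if (length(scores) < 1L) stop("softmax needs at least one score")
  if (any(!is.finite(scores))) stop("softmax scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Fit a feature-concept correlation model
#'
#' Computes the association weight `W(feature, concept)` for every feature
#' unit observed in the labeled sentences against every concept, using one of
#' the three correlation measures, and caches the per-concept log-normalizer
#' `log sum_l exp(W(l, concept))` over the training vocabulary that converts
#' weights into the conditional feature probabilities of
#' [feature_probability()].
#'
#' @param labeled_sentences non-empty list of annotated [al_sentence()]s.
#' @param concept_set the active [concept_set()].
#' @param method `"chi2_yates"`, `"relative_risk"` or `"odds_ratio"`.
#' @param features a [feature_spec()].
#' @param clamp_yates clamp variant of the chi-square (see
#'   [yates_chi_square()]).
#' @return An object of class `correlation_model` with elements `W`
#'   (features x concepts weight matrix), `log_norm`, `vocabulary`,
#'   `concepts`, `method` and `features`.
#' @export
fit_correlation_model <- function(labeled_sentences, concept_set,
                                  method = c("chi2_yates", "relative_risk", "odds_ratio"),
                                  features = feature_spec("ngram", 1L),
                                  clamp_yates = FALSE) {
  method <- match.arg(method)
  if (length(labeled_sentences) == 0L) stop("no labeled sentences to fit on")
  map <- build_tables(labeled_sentences, concept_set, features)
  a <- map$joint
  nf <- map$n_feat; nc <- map$n_concept; N <- map$n
  b <- matrix(nf, nrow(a), ncol(a)) - a
  cc <- matrix(nc, nrow(a), ncol(a), byrow = TRUE) - a
  d <- N - matrix(nf, nrow(a), ncol(a)) - matrix(nc, nrow(a), ncol(a), byrow = TRUE) + a
  W <- switch(method,
              chi2_yates = w_yates(a, b, cc, d, clamp = clamp_yates),
              relative_risk = w_relative_risk(a, b, cc, d),
              odds_ratio = w_odds_ratio(a, b, cc, d))
  W <- matrix(as.numeric(W), nrow(a), ncol(a), dimnames = dimnames(a))
  log_norm <- apply(W, 2L, log_sum_exp)
  structure(list(method = method, features = features, W = W,
                 log_norm = log_norm,
                 vocabulary = rownames(W), concepts = colnames(W),
                 clamp_yates = clamp_yates),
            class = "correlation_model")
}

#' Conditional probability of a feature unit given a concept
#'
#' Softmax of the correlation weight over the training vocabulary of the
#' model's feature kind: `p(f | concept) = exp(W(f, concept)) /
#' sum_l exp(W(l, concept))`, with the sum running over all features seen at
#' fit time. Features outside the vocabulary return 0 here; out-of-vocabulary
#' backoff is a separate step ([oov_weight()]).
#'
#' @param model a fitted [fit_correlation_model()].
#' @param f feature unit (character key).
#' @param concept concept identifier.
#' @return probability in `[0, 1]`.
#' @export
feature_probability <- function(model, f, concept) {
  stopifnot(inherits(model, "correlation_model"))
  if (!(concept %in% model$concepts)) stop("unknown concept: ", concept)
  fi <- match(f, model$vocabulary)
  if (is.na(fi)) return(0)
  exp(model$W[fi, concept] - model$log_norm[[concept]])
}

#' Serialize and reload a correlation model
#'
#' Tab-separated text: two header lines (`#method`, `#features`) followed by
#' one `feature<TAB>concept<TAB>W` line per pair. Weights are written with 17
#' significant digits so the reload is bit-exact.
#'
#' @param model a `correlation_model`.
#' @param path file path.
#' @return `read_correlation_model()` returns the reloaded model.
#' @export
write_correlation_model <- function(model, path) {
  stopifnot(inherits(model, "correlation_model"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0("#method\t", model$method),
               paste("#features", model$features$kind,
                     paste(model$features$order, collapse = ","), sep = "\t")), con)
  if (length(model$vocabulary) > 0L) {
    grid <- expand.grid(f = model$vocabulary, cc = model$concepts,
                        stringsAsFactors = FALSE)
    writeLines(sprintf("%s\t%s\t%.17g", grid$f, grid$cc,
                       model$W[cbind(grid$f, grid$cc)]), con)
  }
  invisible(path)
}

#' @rdname write_correlation_model
#' @export
read_correlation_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1L], "#method\t"))
    stop("malformed correlation model file: ", path)
  method <- sub("^#method\t", "", lines[1L])
  fparts <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  features <- feature_spec(fparts[2L],
                           if (fparts[2L] == "ngram")
                             as.integer(strsplit(fparts[3L], ",")[[1L]]) else 1L)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    W <- matrix(numeric(), 0L, 0L)
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    df <- data.frame(feature = vapply(f, `[[`, "", 1L),
                     concept = vapply(f, `[[`, "", 2L),
                     w = as.numeric(vapply(f, `[[`, "", 3L)))
    vocab <- unique(df$feature); cons <- unique(df$concept)
    W <- matrix(NA_real_, length(vocab), length(cons),
                dimnames = list(vocab, cons))
    W[cbind(df$feature, df$concept)] <- df$w
  }
  structure(list(method = method, features = features, W = W,
                 log_norm = apply(W, 2L, log_sum_exp),
                 vocabulary = rownames(W), concepts = colnames(W),
                 clamp_yates = FALSE),
            class = "correlation_model")
}
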