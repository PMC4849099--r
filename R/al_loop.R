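#' Configuration of the selection loop
#'
#' @param strategy document-ranking strategy.
#' @param batch_fraction per-round batch size as a fraction of the initial
#'   unlabeled pool, in `(0, 1]`; the protocol's default adds 10 percent of
#'   the original training data per round.
#' @param rounds maximum number of rounds (default 10, exhausting the pool at
#'   the default batch fraction).
#' @param seed integer seed controlling the random strategy and any other
#'   randomness.
#' @param inf an [informativity_config()].
#' @param mock_threshold recognition threshold of the mock learner trained
#'   inside the loop.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(strategy = c("informativity", "committee", "entropy",
                                     "gibbs", "random"),
                        batch_fraction = 0.1, rounds = 10L, seed = 1L,
                        inf = informativity_config(), mock_threshold = 5L) {
  strategy <- match.arg(strategy)
  if (!is.finite(batch_fraction) || batch_fraction <= 0 || batch_fraction > 1)
    stop("batch_fraction must lie in (0, 1]")
  rounds <- as.integer(rounds)
  if (is.na(rounds) || rounds < 1L) stop("rounds must be >= 1")
  structure(list(strategy = strategy, batch_fraction = batch_fraction,
                 rounds = rounds, seed = as.integer(seed), inf = inf,
                 mock_threshold = as.integer(mock_threshold)),
            class = "loop_config")
}

# Which statistical models the strategy consumes this round.
needs_models <- function(config) {
  s <- config$strategy; inf <- config$inf
  ngram <- s %in% c("committee", "entropy", "gibbs") ||
    (s == "informativity" && (inf$task == "ner" || inf$alpha > 0))
  pas <- s == "informativity" && inf$task == "event" && inf$beta > 0
  prior <- s %in% c("informativity", "committee")
  list(ngram = ngram, pas = pas, prior = prior)
}

fit_state_models <- function(state) {
  need <- needs_models(state$config)
  sentences <- all_sentences(state$pools$labeled)
  inf <- state$config$inf
  state$prior <- if (need$prior) fit_prior(sentences, state$concept_set) else NULL
  state$ngram_model <- if (need$ngram)
    fit_correlation_model(sentences, state$concept_set, method = inf$method,
                          features = feature_spec("ngram", inf$ngram_order)) else NULL
  state$pas_model <- if (need$pas)
    fit_correlation_model(sentences, state$concept_set, method = inf$method,
                          features = feature_spec("pas")) else NULL
  state
}

#' Initialize the selection loop
#'
#' Trains the base learner and fits the statistical models on the development
#' documents (the initial labeled pool), with the full training pool
#' unlabeled and the round counter at 0.
#'
#' @param dev_documents non-empty initial labeled (development) documents.
#' @param pool_documents initial unlabeled pool.
#' @param concept_set the active [concept_set()].
#' @param config a [loop_config()].
#' @param sim optional similarity provider for OOV backoff.
#' @return An object of class `al_state` with elements `pools`, `learner`,
#'   `prior`, `ngram_model`, `pas_model`, `batch`, `log`.
#' @export
initialize_loop <- function(dev_documents, pool_documents, concept_set, config,
                            sim = NULL) {
  if (length(dev_documents) == 0L) stop("empty development set")
  stopifnot(inherits(config, "loop_config"))
  batch <- ceiling(config$batch_fraction * length(pool_documents))
  if (length(pool_documents) > 0L && batch < 1L)
    stop("batch_fraction too small for this pool")
  state <- structure(list(pools = pool_state(dev_documents, pool_documents, 0L),
                          concept_set = concept_set, config = config,
                          sim = sim, batch = as.integer(batch),
                          learner = mock_train(dev_documents,
                                               config$mock_threshold,
                                               concept_set),
                          prior = NULL, ngram_model = NULL, pas_model = NULL,
                          log = list()),
                     class = "al_state")
  fit_state_models(state)
}

#' Run one selection round
#'
#' Ranks the unlabeled pool with the configured strategy under the models of
#' the current round, moves the top batch (gold annotations attached, i.e. a
#' simulated oracle) into the labeled pool, refits the learner and the
#' statistical models from scratch on the enlarged pool, and logs the
#' selection.
#'
#' @param state an `al_state`.
#' @param ... unused.
#' @return the updated `al_state`.
#' @export
run_round <- function(state, ...) {
  stopifnot(inherits(state, "al_state"))
  if (length(state$pools$unlabeled) == 0L) stop("unlabeled pool is empty")
  cfg <- state$config
  t0 <- proc.time()[["elapsed"]]
  ranked <- rank_pool(state$pools$unlabeled, cfg$strategy,
                      concept_set = state$concept_set, config = cfg$inf,
                      learner = state$learner, prior = state$prior,
                      ngram_model = state$ngram_model,
                      pas_model = state$pas_model, sim = state$sim,
                      seed = cfg$seed + 7919L * (state$pools$round + 1L))
  b <- min(state$batch, length(ranked))
  selected <- ranked[seq_len(b)]
  state$pools <- update_pools(state$pools, selected)
  state$learner <- mock_train(state$pools$labeled, cfg$mock_threshold,
                              state$concept_set)
  state <- fit_state_models(state)
  state$log[[length(state$log) + 1L]] <-
    list(round = state$pools$round, selected = doc_ids(selected),
         elapsed = proc.time()[["elapsed"]] - t0)
  state
}

#' Run a full active-learning simulation
#'
#' Executes the iterative protocol: initialization on the development split,
#' then up to `config$rounds` rounds of rank / select / refit, evaluating the
#' base learner on the fixed test split after every round.
#'
#' @param dev,pool,test disjoint document splits: initial labeled
#'   (development) documents, the unlabeled selection pool, and the fixed
#'   evaluation split.
#' @param concept_set the active [concept_set()].
#' @param config a [loop_config()].
#' @param sim optional similarity provider.
#' @param eval_fun evaluation hook `function(learner, test, concept_set)`;
#'   defaults to sentence-level micro-F1 ([evaluate_recognizer()]).
#' @return A [learning_curve()] with one score per completed round; the
#'   attribute `"log"` carries the per-round selection log.
#' @export
run_simulation <- function(dev, pool, test, concept_set, config, sim = NULL,
                           eval_fun = NULL) {
  ids <- list(doc_ids(dev), doc_ids(pool), doc_ids(test))
  if (anyDuplicated(unlist(ids)))
    stop("dev/pool/test splits must be disjoint")
  if (is.null(eval_fun)) eval_fun <- evaluate_recognizer
  state <- initialize_loop(dev, pool, concept_set, config, sim)
  scores <- numeric(); n_labeled <- integer()
  while (state$pools$round < config$rounds &&
         length(state$pools$unlabeled) > 0L) {
    state <- run_round(state)
    scores <- c(scores, eval_fun(state$learner, test, concept_set))
    n_labeled <- c(n_labeled, length(state$pools$labeled))
  }
  curve <- learning_curve(scores, strategy = config$strategy,
                          n_labeled = n_labeled)
  attr(curve, "log") <- state$log
  curve
}

#' Averaged random-selection reference curve
#'
#' Runs the random strategy once per seed and averages the per-round scores:
#' the reference curve for deficiency.
#'
#' @inheritParams run_simulation
#' @param seeds integer vector of seeds (one run each).
#' @return a [learning_curve()] tagged `"random_average"`.
#' @export
rs_average_curve <- function(dev, pool, test, concept_set, config,
                             seeds = 1:10, eval_fun = NULL) {
  curves <- lapply(seeds, function(sd) {
    cfg <- config
    cfg$strategy <- "random"
    cfg$seed <- as.integer(sd)
    run_simulation(dev, pool, test, concept_set, cfg, eval_fun = eval_fun)
  })
  lens <- vapply(curves, nrow, 0L)
  if (length(unique(lens)) != 1L) stop("random runs produced unequal curve lengths")
  avg <- rowMeans(vapply(curves, curve_scores, numeric(lens[1L])))
  learning_curve(avg, strategy = "random_average",
                 n_labeled = curves[[1L]]$n_labeled)
}

#' Read a flat key-value run configuration
#'
#' YAML file with flat keys `strategy`, `feature_kind`, `method`,
#' `ngram_order`, `delta`, `alpha`, `beta`, `gamma`, `k`, `batch_fraction`,
#' `rounds`, `seed`, `oov_enabled`, `task`, `mock_threshold`; missing keys
#' fall back to the package defaults.
#'
#' @param path configuration file path.
#' @return a [loop_config()].
#' @export
read_al_config <- function(path) {
  kv <- yaml::read_yaml(path)
  if (is.null(kv)) kv <- list()
  pick <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  inf_def <- informativity_config()
  inf <- informativity_config(
    delta = pick("delta", inf_def$delta),
    alpha = pick("alpha", inf_def$alpha),
    beta = pick("beta", inf_def$beta),
    gamma = pick("gamma", inf_def$gamma),
    k = pick("k", inf_def$k),
    feature_kind = pick("feature_kind", inf_def$feature_kind),
    ngram_order = pick("ngram_order", inf_def$ngram_order),
    oov_enabled = pick("oov_enabled", inf_def$oov_enabled),
    method = pick("method", inf_def$method),
    task = pick("task", inf_def$task))
  loop_config(strategy = pick("strategy", "informativity"),
              batch_fraction = pick("batch_fraction", 0.1),
              rounds = pick("rounds", 10L),
              seed = pick("seed", 1L),
              inf = inf,
              mock_threshold = pick("mock_threshold", 5L))
}
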