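---
title: "Committee-based active learning for ontological event and entity extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee-based active learning for ontological event and entity extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activeIE)
```

## The problem

Supervised event-extraction and named-entity systems for the biomedical
literature need manually annotated training corpora, and annotation against a
rich ontology (dozens to hundreds of event, relation and entity concepts) is
the dominant cost. Pool-based active learning addresses this by ranking the
unlabeled documents and sending only the most *informative* ones to the
annotators each round.

`activeIE` implements a committee of two members. The first is the base
recognizer itself (an SVM event extractor or CRF tagger in practice; here an
explicit behavioral contract with a trainable mock). The second is a
statistical estimator of how likely a sentence expresses each ontology
concept. A document is informative when the statistical member assigns high
probability to concepts the base recognizer does **not** extract — the
selection deliberately hunts false negatives, on the argument that correcting
missed events is what most improves a recall-starved extractor.

## The informativity model

For a document $x$ with sentences $S_k$, the score is the sentence average
$I(x) = \frac{1}{\lVert x\rVert}\sum_k I(S_k)$, and per sentence, over the
concept set $\mathcal{E}$:

$$I(S_k,\mathcal{E}) = \sum_{E_i\in\mathcal{E}} I(S_k, E_i),\qquad
I(S_k,E_i)=\begin{cases}0 & E_i \text{ recognized in } S_k\\
p(E_i)\,p(S_k\mid E_i) & \text{otherwise.}\end{cases}$$

The prior $p(E_i)$ is the maximum-likelihood fraction of labeled sentences
annotated with $E_i$ (floored at $10^{-6}$ for unseen concepts). The
likelihood is a softmax across concepts of a correlation score

$$Z(S_k : E_i) = \frac{1}{\mathrm{len}(S_k)}\sum_{f_j \in S_k} p(f_j\mid E_i),$$

where the feature units $f_j$ are either word n-grams or predicate–argument
triples (read from a parser sidecar file; no parser is run here), and
$p(f\mid E_i)$ is itself a softmax, over the training vocabulary, of an
association weight $W(f, E_i)$ computed from a sentence-level 2×2 contingency
table: Yates-corrected chi-square (default), relative risk, or odds ratio.

Two optional additions complete the score. A participant term $\delta\,T$
adds the count $T$ of gene/protein name mentions in the sentence — evidence
that an event may be present even when no trigger vocabulary matches.
Out-of-vocabulary backoff reconstructs the weight of an unseen unigram from
its top-$k$ most similar known words, $W_{\mathrm{OOV}}(w,E_i) = \sum_{top\text{-}k}
W(w',E_i)\,\mathrm{Sim}(w,w')$, with similarities supplied by a word-vector
file or a pairwise table. The full score is the linear combination

$$I(S_k) = \alpha\, I(S_k,\mathcal{E},NG_{\mathrm{OOV}}) +
\beta\, I(S_k,\mathcal{E},PAS) + \gamma\,\delta\,T .$$

The named-entity adaptation is the same code path with an entity concept set
and n-gram features only; configuration validation enforces the restriction.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.25 | weight of one participant mention (dimensionless score units) |
| `alpha, beta, gamma` | 0.1, 0.1, 0.8 | combination weights of the n-gram, PAS and participant terms |
| `k` | 25 | OOV neighbors |
| `method` | `chi2_yates` | association weight on the 2×2 table |
| `ngram_order` | 1 | unigrams; `c(1, 2)` mixes orders |
| `batch_fraction` | 0.1 | per-round batch as a fraction of the initial pool |
| `rounds` | 10 | selection rounds (10 × 10 % exhausts the pool) |
| `mock_threshold` | 5 | co-annotation count the mock recognizer requires |

The first five are the tuned operating point of the underlying method; all
are overridable through `informativity_config()` or the flat YAML
configuration file of `read_al_config()`.

The mock recognizer's threshold of 5 comes from a collision analysis of the
default synthetic corpus: planted keywords reach expected co-annotation
counts of 8–9 at full pool while a background token's expected co-count with
any one concept is below 1, so a threshold of 5 keeps accidental triggers to
a Poisson tail of a fraction of a percent while letting every true trigger
cross during the run. Lower thresholds flood the learner with false triggers
as the pool grows; higher ones freeze recall.

## Baseline strategies

Alongside the proposed score, `rank_pool()` offers the conventional committee
(summed absolute difference between the statistical posterior, computed for
all sentences without filtering, and the recognizer's distribution — its CRF
marginals when it has a probability capability, else a softmax of the
difference-2 SVM margin), entropy and Gibbs-error uncertainty baselines (sum
over in-vocabulary n-gram occurrences and concepts of $H(p)$ or $1-p^2$ with
$p$ the feature–concept probability), and seeded uniform random selection.
Two notes on readings the underlying formulation leaves open: the
difference-2 margin is a per-sentence quantity, identical for every concept,
so a learner without probability output contributes a uniform distribution to
the disagreement; and the entropy at a feature–concept node is taken as the
binary entropy of the feature–concept probability, the only probability
available at that node. Batch selection takes the top *b* of the ranking
with ties broken by ascending document id; no diversity term is applied.

## The synthetic benchmark

`generate_corpus()` draws corpora that have exactly the statistical structure
the estimator exploits: each concept owns a small disjoint trigger
vocabulary; annotated sentences emit a trigger with probability 0.9 on top of
uniform background noise (500 types); participant mentions arrive at Poisson
rate 1.5 in annotated vs 0.2 in background sentences, from a wide (200-name)
lexicon, since gene names are an open class and a narrow lexicon would turn
individual names into spurious concept triggers; up to two concepts per
sentence exercise the multi-event case; predicate–argument units are proxied
by adjacent-token pairs, which exercises the PAS code path without any claim
to syntax. Documents are abstract-sized (3–8 sentences), split 15/70/15 into
dev/train/test, and every draw is reproducible to the byte from the seed.

Concept frequencies default to uniform. This is a deliberate compromise:
real ontological annotation is heavily skewed (a `"zipf"` option and
arbitrary weight vectors are provided), but with 200 documents a 1/rank skew
pushes the rarest concepts below any workable recognition threshold of the
count-based mock — selection then tunnels on unlearnable concepts and
keyword recovery degrades. Uniform frequencies keep every concept learnable
at this scale. The flip side, worth stating plainly: with symmetric priors
the *unfiltered* informativity $\sum_i p(E_i)\,p(S_k|E_i)$ is constant across
sentences (the likelihood sums to one over concepts), so document ranking is
driven by the participant term and by recognizer filtering. The event-mode
simulation, whose score includes $\gamma\delta T$, beats random selection
clearly; the NER-mode simulation, which by construction uses n-grams alone,
hovers near parity with random under these symmetric conditions — a
structural property of the score under uniform priors, not a defect of the
search loop. On skewed real corpora the prior term is active.

What the generator does **not** emulate: natural token frequency
distributions, discourse structure, annotation noise, real syntax behind the
PAS units, or embedding geometry (the synthetic similarity provider links
held-out trigger synonyms to their concept's retained keywords at similarity
0.85–0.95 and to other concepts at ≤ 0.1). Passing the closed-loop checks
therefore demonstrates the machinery is correct and the selection signal
points the right way under the model's own assumptions; it does not predict
effect sizes on real corpora.

## Numerical and policy choices

* **Evidence term.** The Bayes evidence $p(S_k)$ is treated as the constant
  1: scores are unnormalized products $p(E_i)p(S_k|E_i)$. Normalizing per
  sentence would force every fully-unrecognized sentence to the same total
  and erase the ranking.
* **Softmax stability.** All softmaxes subtract the maximum; the per-concept
  vocabulary normalizer is a cached log-sum-exp. Chi-square weights can reach
  the hundreds, so nothing exponentiates an uncentred weight.
* **OOV probability.** $W_{\mathrm{OOV}}$ lives on the raw weight scale and can
  exceed every in-vocabulary weight; mapping it through
  $\exp(W_{\mathrm{OOV}} - \log Z_c)$ could overflow and exceed 1. The unknown
  word is instead added to the normalizing universe for its own probability,
  $p = 1/(1 + \exp(\log Z_c - W_{\mathrm{OOV}}))$, which is bounded, monotone
  in $W_{\mathrm{OOV}}$, and agrees with the in-vocabulary scale for small
  weights. Backoff applies to unigrams only; unknown higher-order n-grams
  score 0.
* **Zero cells and degenerate tables.** Relative risk and odds ratio apply
  the Haldane–Anscombe +0.5 to all four cells only when some cell is zero.
  The chi-square keeps its printed form, squaring $(|ad-bc| - N/2)$ even when
  $|ad-bc| < N/2$; a `clamp` flag exposes the textbook variant. Inside a
  whole-vocabulary fit, a pair with a zero marginal gets weight 0 (no
  association signal either way); the scalar function treats it as an error.
* **Degenerate sentences.** Zero-length sentences score 0 rather than
  erroring inside document averages; empty documents are not rankable.
* **Ties.** Document ranking breaks ties by ascending id; top-$N$ concept
  prediction and neighbor queries break ties by identifier. Reruns are
  byte-identical given the seed.
* **Refits.** Learner, priors and correlation models are refit from scratch
  each round from the current labeled pool only; strategies that do not
  consume a model (random) skip its fit.
* **Curve metric.** Learning curves record the mock recognizer's
  sentence-level micro-F1 on the fixed test split. The deficiency ratio
  $\sum_t(\mathrm{acc}_n(REF)-\mathrm{acc}_t(AL)) /
  \sum_t(\mathrm{acc}_n(REF)-\mathrm{acc}_t(REF))$ uses only differences
  against the reference's final score, so any monotone quality measure gives
  the same reading; values below 1 mean the strategy beats the reference.

## Problem sizes

The test suite and the acceptance script run the full default conditions:
200-document corpora, 10 concepts × 5 keywords, 500 background types,
10-round loops with a 10-seed random reference, and 5-seed averages for
keyword recovery. A 60-document corpus backs the loop-mechanics tests where
only bookkeeping, not signal, is under test.

## Known limitations

The mock recognizer is a token-count gate: it has no notion of argument
structure, so it cannot reproduce effect sizes reported with real extraction
systems, only ordering behavior. Softmaxing raw chi-square weights
concentrates nearly all of a concept's feature probability on its single
strongest keyword, which mutes the contribution of secondary triggers; this
is inherent to using the raw association scale inside the softmax.
Cross-sentence events are assigned to their trigger's sentence. The standoff
reader covers the dialect written by this package plus equivalence and
modification lines (ignored); it is not a full shared-task format validator.
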