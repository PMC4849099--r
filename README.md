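# activeIE

Pool-based active learning for biomedical information extraction tasks whose
annotations name the concepts of an ontology — multi-type event extraction,
binary relations, or named-entity recognition.

Manually annotating training corpora against a rich ontology is the dominant
cost of building supervised extraction systems. `activeIE` ranks the
unlabeled documents so annotators label the most useful ones first. Its core
is a two-member committee: the base recognizer itself (behind a pluggable
contract) and a statistical estimator of how likely each sentence expresses
each concept. A document scores high when the statistical member assigns
probability to concepts the recognizer fails to extract — selection
deliberately targets false negatives.

## The score

For a document `x` with sentences `S_k`:

```
I(x)        = (1/||x||) Σ_k I(S_k)
I(S_k, E_i) = 0                      if E_i is recognized in S_k
            = p(E_i) · p(S_k | E_i)  otherwise,  summed over the concept set
```

with maximum-likelihood concept priors `p(E_i)` and a likelihood
`p(S_k|E_i) = σ(Z(S_k:E_i))` built from feature–concept association weights:

```
Z(S_k:E_i) = (1/len(S_k)) Σ_j p(f_j | E_i),   p(f|E_i) = σ(W(f, E_i))
```

`W` is computed per (feature, concept) pair from a sentence-level 2×2
contingency table by Yates-corrected chi-square, relative risk, or odds
ratio. Feature units are word n-grams or predicate–argument triples.
Optional terms add event-participant evidence (`δ·T`, `T` = gene/protein
mentions) and out-of-vocabulary backoff through word similarity
(`W_OOV(w,E) = Σ_top-k W(w',E)·Sim(w,w')`), combined as
`α·I_ngram + β·I_pas + γ·δ·T` (defaults 0.1 / 0.1 / 0.8, δ = 0.25, k = 25).

Committee-disagreement, entropy, Gibbs-error and random strategies are
included as baselines, and learning curves are compared with the
**deficiency** ratio — below 1 means the strategy reaches the reference's
final accuracy faster than random selection does.

Everything runs closed-loop without external systems: a seeded generator
produces standoff-annotated corpora (BioNLP-style `.txt`/`.a1`/`.a2` plus
`.pas` sidecars) with planted trigger vocabularies, and a trainable mock
recognizer stands in for the extraction system. Adapters for real systems
only need to implement four small generics (see `?recognizer-contract`).

## Worked example

```r
library(activeIE)

corp <- generate_corpus(synth_spec(seed = 42))   # 200 docs, 10 concepts
cfg  <- loop_config(strategy = "informativity", seed = 42)

al  <- run_simulation(corp$dev, corp$train, corp$test, corp$concept_set, cfg)
ref <- rs_average_curve(corp$dev, corp$train, corp$test, corp$concept_set,
                        cfg, seeds = 1:10)

round(al$score, 3)
#>  [1] 0.128 0.324 0.625 0.667 0.725 0.831 0.896 0.902 0.897 0.917
round(ref$score, 3)
#>  [1] 0.061 0.196 0.343 0.507 0.629 0.731 0.785 0.845 0.898 0.917
deficiency(al, ref)
#> 0.693
```

The two curves are the mock recognizer's sentence-level micro-F1 on the fixed
test split after each of 10 rounds (10 % of the pool labeled per round) under
informativity-guided vs. averaged random selection. Both end at the same
point — after round 10 every document is labeled — but the informativity
curve gets there faster; the deficiency of 0.693 summarizes that advantage
(1.0 would be parity with random).

The fitted association weights are inspectable; each concept's planted
trigger keywords dominate its ranking:

```r
m <- fit_correlation_model(all_sentences(c(corp$dev, corp$train)), corp$concept_set)
head(sort(m$W[, "E03"], decreasing = TRUE), 3)
#>  e03kw05  e03kw03  e03kw01
#> 215.3238 167.1868 119.3698
```

A thin command-line front end (`inst/scripts/activeie`) exposes the same
pipeline as `synth`, `rank`, `simulate` and `deficiency` subcommands driven
by a flat YAML configuration.

## Scope notes

The package abstracts the base recognizer behind a contract rather than
shipping adapters for any particular extraction system, consumes (never
produces) predicate–argument structures, and treats word similarity as an
input resource. The methods vignette
(`vignettes/informativity-active-learning.Rmd`) documents the model,
parameter defaults, numerical choices, and the known limitations of the
synthetic benchmark.
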