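Package: activeIE
Title: Committee-Based Active Learning for Ontological Event and Entity Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pool-based active learning for biomedical information extraction
    tasks annotated against an ontology (events, relations, named entities).
    Implements a statistical informativity estimator built on sentence-level
    n-gram/predicate-argument co-occurrence statistics (Yates chi-square,
    relative risk, odds ratio), a two-member committee with a pluggable base
    recognizer, entropy and Gibbs-error baselines, out-of-vocabulary backoff
    via word similarity, the iterative selection loop, and the deficiency
    metric for learning-curve comparison. Ships a seeded synthetic corpus
    generator (BioNLP-style standoff format) and a trainable mock recognizer
    so the whole pipeline runs closed-loop without external systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
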