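test_that("tokenization strips punctuation, lower-cases, drops empties", {
  expect_identical(tokenize_words("The cat, (quickly) -- ran."),
                   c("the", "cat", "quickly", "ran"))
  expect_identical(tokenize_words("   "), character())
  s <- al_sentence("s", "IL-2 binds; STAT5!")
  expect_identical(s$word_count, length(s$tokens))
})

test_that("n-gram extraction honors order, excludes lower orders, keeps multiplicity", {
  s <- make_sentence(c("a", "b", "c"))
  expect_identical(extract_ngrams(s, 1L), c("a", "b", "c"))
  expect_identical(extract_ngrams(s, 2L), c("a b", "b c"))
  expect_identical(sort(extract_ngrams(s, c(1L, 2L))),
                   sort(c("a", "b", "c", "a b", "b c")))
  expect_identical(extract_ngrams(make_sentence(c("a", "a")), 1L), c("a", "a"))
  expect_error(extract_ngrams(s, 0L), "order")
  # window count is max(0, w - n + 1)
  for (w in 0:5) for (n in 1:4) {
    s2 <- make_sentence(rep("tok", w), id = paste0("w", w))
    expect_length(extract_ngrams(s2, n), max(0L, w - n + 1L))
  }
})

test_that("concept sets validate identifiers", {
  expect_error(concept_set(character()), "at least one")
  expect_error(concept_set(c("A", "A")), "unique")
  expect_error(concept_set(c("A", "")), "non-empty")
  cs <- concept_set(c("A", "B"), kind = c("event", "entity"))
  expect_identical(cs$kind, c("event", "entity"))
})

test_that("pool updates move documents, increment the round, conserve totals", {
  docs <- lapply(1:5, function(i) make_doc(paste0("d", i), list(c("a", "b"))))
  st <- pool_state(labeled = docs[1], unlabeled = docs[2:5])

  st0 <- update_pools(st, list())
  expect_identical(st0$round, 1L)
  expect_length(st0$unlabeled, 4L)

  st1 <- update_pools(st, docs[2])
  expect_setequal(doc_ids(st1$labeled), c("d1", "d2"))
  expect_setequal(doc_ids(st1$unlabeled), c("d3", "d4", "d5"))
  expect_error(update_pools(st1, docs[2]), "not in the unlabeled pool")

  # conservation over random selection schedules
  withr::with_seed(99, {
    for (rep in 1:5) {
      st <- pool_state(labeled = list(), unlabeled = docs)
      while (length(st$unlabeled) > 0L) {
        pick <- sample(seq_along(st$unlabeled),
                       sample(seq_along(st$unlabeled), 1L))
        st <- update_pools(st, st$unlabeled[pick])
        expect_length(intersect(doc_ids(st$labeled), doc_ids(st$unlabeled)), 0L)
        expect_identical(length(st$labeled) + length(st$unlabeled), 5L)
      }
      expect_setequal(doc_ids(st$labeled), doc_ids(docs))
    }
  })
})

test_that("standoff write/read round-trips synthetic documents of all kinds", {
  cs <- concept_set(c("Reg", "Phos", "Bind", "PartOf", "Gene"),
                    kind = c("event", "event", "relation", "relation", "entity"))
  withr::with_seed(4711, {
    for (rep in 1:5) {
      docs <- lapply(1:3, function(i) random_roundtrip_doc(sprintf("doc%d", i), cs))
      dir <- withr::local_tempdir()
      write_standoff_corpus(docs, dir, cs)
      back <- read_standoff_corpus(dir, cs)
      expect_length(back, 3L)
      for (i in seq_along(docs)) expect_same_document(docs[[i]], back[[i]])
    }
  })
})

test_that("single-annotation corpus reads to the expected gold set", {
  dir <- withr::local_tempdir()
  writeLines(c("foo bar baz", "qux quux"), file.path(dir, "doc1.txt"))
  writeLines(c("T1\tC 0 3\tfoo", "E1\tC:T1"), file.path(dir, "doc1.a2"))
  docs <- read_standoff_corpus(dir, concept_set("C"))
  expect_length(docs, 1L)
  expect_identical(docs[[1]]$sentences[[1]]$gold_concepts, "C")
  expect_identical(docs[[1]]$sentences[[2]]$gold_concepts, character())
})

test_that("empty directory yields an empty corpus", {
  dir <- withr::local_tempdir()
  expect_identical(read_standoff_corpus(dir, concept_set("C")), list())
  write_standoff_corpus(list(), dir, concept_set("C"))
  expect_length(list.files(dir, pattern = "\\.txt$"), 0L)
})

test_that("reader rejects malformed lines, bad offsets, unknown concepts", {
  cs <- concept_set("C")
  mk <- function(a2_lines) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    writeLines("foo bar", file.path(dir, "d.txt"))
    writeLines(a2_lines, file.path(dir, "d.a2"))
    dir
  }
  expect_error(read_standoff_corpus(mk("garbage line"), cs), "unrecognized|malformed")
  expect_error(read_standoff_corpus(mk("T1\tC 0 99\tfoo"), cs), "outside text")
  expect_error(read_standoff_corpus(mk(c("T1\tD 0 3\tfoo", "E1\tD:T1")), cs),
               "unknown concept identifier")
  expect_error(read_standoff_corpus(mk("T1\tD 0 3\tfoo"), cs),
               "unknown concept identifier")
})

test_that("PAS sidecars attach units to the right sentences", {
  dir <- withr::local_tempdir()
  writeLines(c("a b", "c d"), file.path(dir, "d.txt"))
  writeLines(c("2\tc\targ\td", "1\ta\targ\tb"), file.path(dir, "d.pas"))
  doc <- read_standoff_corpus(dir, concept_set("C"))[[1]]
  expect_equal(unname(doc$sentences[[1]]$pas_units), cbind("a", "arg", "b"))
  expect_equal(unname(doc$sentences[[2]]$pas_units), cbind("c", "arg", "d"))
  writeLines("9\tx\targ\ty", file.path(dir, "d.pas"))
  expect_error(read_standoff_corpus(dir, concept_set("C")), "out of range")
})
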