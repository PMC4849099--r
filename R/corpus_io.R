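#' Define the ontology concept set being tracked
#'
#' A concept set lists the ontology concepts whose expression in sentences the
#' framework tracks: event types (each anchored by a trigger word), binary
#' relation types, or named-entity types. Events and relations are handled the
#' same way throughout; an entity-only concept set switches the framework into
#' its named-entity-recognition mode.
#'
#' @param ids character vector of unique, non-empty concept identifiers.
#' @param kind concept kind, one of `"event"`, `"relation"`, `"entity"`;
#'   recycled to the length of `ids`.
#' @return An object of class `concept_set`: a data frame with columns `id`
#'   and `kind`.
#' @examples
#' concept_set(c("GeneRegulation", "Phosphorylation"))
#' @export
concept_set <- function(ids, kind = "event") {
  ids <- as.character(ids)
  if (length(ids) < 1L) stop("a concept set needs at least one concept")
  if (anyDuplicated(ids)) stop("concept identifiers must be unique")
  if (any(!nzchar(ids))) stop("concept identifiers must be non-empty")
  kind <- rep_len(match.arg(kind, c("event", "relation", "entity"), several.ok = TRUE),
                  length(ids))
  structure(data.frame(id = ids, kind = kind, stringsAsFactors = FALSE),
            class = c("concept_set", "data.frame"))
}

concept_ids <- function(cs) cs$id

is_entity_set <- function(cs) all(cs$kind == "entity")

#' Tokenize raw sentence text
#'
#' Splits on whitespace, strips leading/trailing punctuation from each token,
#' lower-cases, and drops tokens that become empty. This fixed, deterministic
#' tokenization defines `word_count` everywhere in the package.
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize_words <- function(text) {
  toks <- unlist(strsplit(text, "[[:space:]]+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  tolower(toks[nzchar(toks)])
}

#' Construct an annotated sentence
#'
#' @param id sentence identifier, unique within its document.
#' @param text raw sentence text (one line of the source text file).
#' @param gold_concepts character vector (multiset) of concept identifiers
#'   annotated on the sentence.
#' @param pas_units character matrix with three columns
#'   (predicate, relation label, argument); zero rows if no predicate-argument
#'   units are attached.
#' @param ne_count non-negative integer: number of participant (gene/protein)
#'   name mentions in the sentence, written `T` in the participant term
#'   `delta * T` of the informativity score.
#' @param tokens token vector; defaults to [tokenize_words()] of `text`.
#' @return An object of class `al_sentence`.
#' @export
al_sentence <- function(id, text, gold_concepts = character(),
                        pas_units = NULL, ne_count = 0L,
                        tokens = tokenize_words(text)) {
  if (is.null(pas_units)) pas_units <- matrix(character(), 0L, 3L)
  pas_units <- as.matrix(pas_units)
  if (nrow(pas_units) > 0L && ncol(pas_units) != 3L)
    stop("pas_units must have three columns (predicate, relation, argument)")
  ne_count <- as.integer(ne_count)
  if (is.na(ne_count) || ne_count < 0L) stop("ne_count must be >= 0")
  structure(list(id = as.character(id), text = as.character(text),
                 tokens = as.character(tokens),
                 word_count = length(tokens),
                 gold_concepts = as.character(gold_concepts),
                 pas_units = pas_units, ne_count = ne_count),
            class = "al_sentence")
}

#' Construct a document
#'
#' A document is an ordered list of sentences; its size (number of sentences)
#' is the normalizer of the document-level informativity average.
#'
#' @param id document identifier.
#' @param sentences list of [al_sentence()] objects, at least one, with unique
#'   sentence ids.
#' @return An object of class `al_document`.
#' @export
al_document <- function(id, sentences) {
  if (length(sentences) < 1L) stop("a document needs at least one sentence")
  sids <- vapply(sentences, function(s) s$id, "")
  if (anyDuplicated(sids)) stop("sentence ids must be unique within a document")
  structure(list(id = as.character(id), sentences = sentences),
            class = "al_document")
}

#' Document accessors
#'
#' `document_size()` is the number of sentences, `doc_ids()` the identifiers
#' of a document list, `all_sentences()` the flattened sentence list of a
#' document list.
#'
#' @param doc an [al_document()].
#' @param docs list of documents.
#' @return size, character vector of ids, or list of sentences.
#' @export
document_size <- function(doc) length(doc$sentences)

#' @rdname document_size
#' @export
doc_ids <- function(docs) vapply(docs, function(d) d$id, "")

#' @rdname document_size
#' @export
all_sentences <- function(docs) {
  unlist(lapply(docs, function(d) d$sentences), recursive = FALSE)
}

#' Labeled/unlabeled document pools
#'
#' @param labeled,unlabeled lists of documents; a document id may appear in at
#'   most one pool.
#' @param round non-negative round counter `t`.
#' @return An object of class `pool_state`.
#' @export
pool_state <- function(labeled, unlabeled, round = 0L) {
  li <- doc_ids(labeled); ui <- doc_ids(unlabeled)
  if (length(intersect(li, ui)) > 0L)
    stop("labeled and unlabeled pools must be disjoint")
  if (anyDuplicated(c(li, ui))) stop("duplicate document ids across pools")
  structure(list(labeled = labeled, unlabeled = unlabeled,
                 round = as.integer(round)),
            class = "pool_state")
}

#' Move selected documents from the unlabeled to the labeled pool
#'
#' One pool update of the active-learning protocol: the selected batch joins
#' the labeled pool together with its (oracle) annotations, the round counter
#' increments, and the total number of documents is conserved.
#'
#' @param state a [pool_state()].
#' @param selected list of documents currently in the unlabeled pool.
#' @return The updated `pool_state`.
#' @export
update_pools <- function(state, selected) {
  stopifnot(inherits(state, "pool_state"))
  sel_ids <- doc_ids(selected)
  ui <- doc_ids(state$unlabeled)
  missing <- setdiff(sel_ids, ui)
  if (length(missing) > 0L)
    stop("selected document(s) not in the unlabeled pool: ",
         paste(missing, collapse = ", "))
  keep <- !(ui %in% sel_ids)
  pool_state(labeled = c(state$labeled, state$unlabeled[!keep]),
             unlabeled = state$unlabeled[keep],
             round = state$round + 1L)
}

#' Extract n-gram feature units from a sentence
#'
#' Contiguous token windows of exactly the requested order(s). An order of 2
#' yields bigrams only (no unigrams); pass `order = c(1, 2)` for the mixed
#' unigram+bigram feature set. Multi-token n-grams are encoded as
#' space-joined strings; multiplicity is preserved.
#'
#' @param sentence an [al_sentence()].
#' @param order integer vector of n-gram orders, all >= 1.
#' @return character vector (multiset) of n-gram feature units.
#' @examples
#' s <- al_sentence("s1", "a b c")
#' extract_ngrams(s, 2)  # "a b", "b c"
#' @export
extract_ngrams <- function(sentence, order = 1L) {
  order <- as.integer(order)
  if (length(order) < 1L || any(is.na(order)) || any(order < 1L))
    stop("n-gram order must be >= 1")
  toks <- sentence$tokens
  out <- character()
  for (n in sort(unique(order))) {
    w <- length(toks) - n + 1L
    if (w < 1L) next
    if (n == 1L) {
      out <- c(out, toks)
    } else {
      grams <- vapply(seq_len(w), function(i) paste(toks[i:(i + n - 1L)], collapse = " "), "")
      out <- c(out, grams)
    }
  }
  out
}

# Predicate-argument feature units as space-joined triples.
pas_features <- function(sentence) {
  p <- sentence$pas_units
  if (nrow(p) == 0L) return(character())
  paste(p[, 1L], p[, 2L], p[, 3L])
}

#' Feature extraction specification
#'
#' @param kind `"ngram"` or `"pas"`.
#' @param order n-gram order(s); ignored for `"pas"`.
#' @return A `feature_spec` list consumed by [fit_correlation_model()].
#' @export
feature_spec <- function(kind = c("ngram", "pas"), order = 1L) {
  kind <- match.arg(kind)
  if (kind == "ngram" && (length(order) < 1L || any(order < 1L)))
    stop("n-gram order must be >= 1")
  structure(list(kind = kind, order = as.integer(order)), class = "feature_spec")
}

feature_extractor <- function(spec) {
  if (spec$kind == "ngram") {
    function(sentence) extract_ngrams(sentence, spec$order)
  } else {
    pas_features
  }
}

## ---------------------------------------------------------------------------
## Standoff corpus I/O
##
## Dialect: <docid>.txt is UTF-8 with one sentence per line; offsets are
## 0-based half-open over the raw text file. <docid>.a1 holds entity term
## lines "Tn<TAB>Type start end<TAB>surface"; <docid>.a2 holds trigger terms
## plus event lines "En<TAB>Type:Ttrigger ..." and relation lines
## "Rn<TAB>Type Arg1:Tx Arg2:Ty". A term typed "Entity" is a structural
## anchor (used for relation arguments); terms typed with `ne_type` count as
## participant name mentions. "*" (equivalence) and "M" lines are ignored.
## An optional <docid>.pas sidecar carries predicate-argument units as
## "sentence_index<TAB>predicate<TAB>relation<TAB>argument" (1-based index).

#' Write documents as a standoff-annotated corpus
#'
#' @param documents list of [al_document()] objects.
#' @param directory output directory (created if missing).
#' @param concept_set the [concept_set()] whose kinds decide how each gold
#'   concept is serialized (entity term, event + trigger, or relation).
#' @param ne_type term type used for participant name mentions.
#' @return Invisibly, the directory.
#' @seealso [read_standoff_corpus()] for the inverse operation.
#' @export
write_standoff_corpus <- function(documents, directory, concept_set,
                                  ne_type = "Protein") {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  kind_of <- setNames(concept_set$kind, concept_set$id)
  for (doc in documents) {
    texts <- vapply(doc$sentences, function(s) s$text, "")
    starts <- c(0L, cumsum(nchar(texts, type = "bytes") + 1L))[seq_along(texts)]
    a1 <- character(); a2 <- character(); tn <- 0L; en <- 0L; rn <- 0L
    pas <- character()
    for (k in seq_along(doc$sentences)) {
      s <- doc$sentences[[k]]
      first_word <- sub("[[:space:]].*$", "", s$text)
      st <- starts[k]; ed <- st + nchar(first_word, type = "bytes")
      anchor_line <- function(type) {
        tn <<- tn + 1L
        sprintf("T%d\t%s %d %d\t%s", tn, type, st, ed, first_word)
      }
      if (s$ne_count > 0L)
        for (i in seq_len(s$ne_count)) a1 <- c(a1, anchor_line(ne_type))
      rel_anchor <- NA_character_
      for (cc in s$gold_concepts) {
        kd <- kind_of[[cc]]
        if (is.null(kd) || is.na(kd)) stop("unknown concept identifier: ", cc)
        if (kd == "entity") {
          a1 <- c(a1, anchor_line(cc))
        } else if (kd == "event") {
          a2 <- c(a2, anchor_line(cc))
          en <- en + 1L
          a2 <- c(a2, sprintf("E%d\t%s:T%d", en, cc, tn))
        } else { # relation: both arguments on a shared "Entity" anchor
          if (is.na(rel_anchor)) {
            a1 <- c(a1, anchor_line("Entity"))
            rel_anchor <- sprintf("T%d", tn)
          }
          rn <- rn + 1L
          a2 <- c(a2, sprintf("R%d\t%s Arg1:%s Arg2:%s", rn, cc, rel_anchor, rel_anchor))
        }
      }
      if (nrow(s$pas_units) > 0L)
        pas <- c(pas, sprintf("%d\t%s\t%s\t%s", k,
                              s$pas_units[, 1L], s$pas_units[, 2L], s$pas_units[, 3L]))
    }
    base <- file.path(directory, doc$id)
    writeLines(texts, paste0(base, ".txt"), useBytes = TRUE)
    writeLines(a1, paste0(base, ".a1"), useBytes = TRUE)
    writeLines(a2, paste0(base, ".a2"), useBytes = TRUE)
    if (length(pas) > 0L) writeLines(pas, paste0(base, ".pas"), useBytes = TRUE)
  }
  invisible(directory)
}

#' Read a standoff-annotated corpus
#'
#' Parses the standoff dialect described in [write_standoff_corpus()] and
#' assigns every annotation to the sentence containing the start offset of its
#' trigger (events), first argument (relations), or term (entities).
#'
#' @param directory corpus directory containing `<docid>.txt` plus optional
#'   `.a1`, `.a2` and `.pas` files.
#' @param concept_set the active [concept_set()]; annotation types outside it
#'   (other than the NE type and `"Entity"` anchors) raise an error.
#' @param ne_type term type counted as a participant name mention.
#' @return list of [al_document()] objects, ordered by document id.
#' @export
read_standoff_corpus <- function(directory, concept_set, ne_type = "Protein") {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  txts <- sort(list.files(directory, pattern = "\\.txt$"))
  lapply(txts, function(fn) {
    docid <- sub("\\.txt$", "", fn)
    read_standoff_document(directory, docid, concept_set, ne_type)
  })
}

read_standoff_document <- function(directory, docid, concept_set, ne_type) {
  txt_path <- file.path(directory, paste0(docid, ".txt"))
  texts <- readLines(txt_path)
  full <- paste(texts, collapse = "\n")
  starts <- c(0L, cumsum(nchar(texts, type = "bytes") + 1L))[seq_along(texts)]
  n_total <- nchar(full, type = "bytes")
  sentence_of <- function(offset) findInterval(offset, starts)

  terms <- list()     # id -> list(type, start)
  gold <- vector("list", length(texts))
  for (k in seq_along(gold)) gold[[k]] <- character()
  ne <- integer(length(texts))
  referenced <- character()

  parse_ann <- function(path) {
    if (!file.exists(path)) return(invisible())
    lines <- readLines(path)
    for (li in seq_along(lines)) {
      line <- lines[li]
      if (!nzchar(line)) next
      bad <- function(why) stop(sprintf("%s line %d: %s: %s", basename(path), li, why, line))
      fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      tag <- substr(fields[1L], 1L, 1L)
      if (tag == "T") {
        if (length(fields) < 2L) bad("malformed term line")
        hdr <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
        if (length(hdr) != 3L) bad("malformed term header")
        st <- suppressWarnings(as.integer(hdr[2L]))
        ed <- suppressWarnings(as.integer(hdr[3L]))
        if (is.na(st) || is.na(ed) || st >= ed) bad("malformed term offsets")
        if (st < 0L || ed > n_total) bad("annotation offset outside text")
        terms[[fields[1L]]] <<- list(type = hdr[1L], start = st)
      } else if (tag == "E") {
        if (length(fields) < 2L) bad("malformed event line")
        first_arg <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]][1L]
        kv <- strsplit(first_arg, ":", fixed = TRUE)[[1L]]
        if (length(kv) != 2L) bad("malformed event trigger reference")
        type <- kv[1L]; tref <- kv[2L]
        if (!(type %in% concept_set$id)) stop("unknown concept identifier: ", type)
        trig <- terms[[tref]]
        if (is.null(trig)) bad(paste0("undefined trigger ", tref))
        referenced <<- c(referenced, tref)
        k <- sentence_of(trig$start)
        gold[[k]] <<- c(gold[[k]], type)
      } else if (tag == "R") {
        if (length(fields) < 2L) bad("malformed relation line")
        parts <- strsplit(fields[2L], " ", fixed = TRUE)[[1L]]
        if (length(parts) < 2L) bad("malformed relation arguments")
        type <- parts[1L]
        if (!(type %in% concept_set$id)) stop("unknown concept identifier: ", type)
        a1ref <- strsplit(parts[2L], ":", fixed = TRUE)[[1L]]
        if (length(a1ref) != 2L) bad("malformed relation argument")
        arg <- terms[[a1ref[2L]]]
        if (is.null(arg)) bad(paste0("undefined argument ", a1ref[2L]))
        referenced <<- c(referenced, vapply(parts[-1L], function(p)
          strsplit(p, ":", fixed = TRUE)[[1L]][2L], ""))
        k <- sentence_of(arg$start)
        gold[[k]] <<- c(gold[[k]], type)
      } else if (tag == "*" || tag == "M") {
        # equivalence / modification lines: parsed and ignored
      } else {
        bad("unrecognized annotation line")
      }
    }
    invisible()
  }
  parse_ann(file.path(directory, paste0(docid, ".a1")))
  parse_ann(file.path(directory, paste0(docid, ".a2")))

  entity_concepts <- concept_set$id[concept_set$kind == "entity"]
  for (tid in names(terms)) {
    tm <- terms[[tid]]
    k <- sentence_of(tm$start)
    if (tm$type %in% entity_concepts) {
      gold[[k]] <- c(gold[[k]], tm$type)
    } else if (tm$type == ne_type) {
      ne[k] <- ne[k] + 1L
    } else if (tm$type == "Entity" || tid %in% referenced) {
      # structural anchor or event trigger: no concept of its own
    } else {
      stop("unknown concept identifier: ", tm$type)
    }
  }

  pas_by_sentence <- read_pas_sidecar(file.path(directory, paste0(docid, ".pas")),
                                      length(texts))
  sentences <- lapply(seq_along(texts), function(k) {
    al_sentence(id = paste0(docid, ":", k), text = texts[k],
                gold_concepts = gold[[k]], pas_units = pas_by_sentence[[k]],
                ne_count = ne[k])
  })
  al_document(docid, sentences)
}

# Read a <docid>.pas sidecar: list of 3-column matrices, one per sentence.
read_pas_sidecar <- function(path, n_sentences) {
  out <- replicate(n_sentences, matrix(character(), 0L, 3L), simplify = FALSE)
  if (!file.exists(path)) return(out)
  lines <- readLines(path)
  for (li in seq_along(lines)) {
    if (!nzchar(lines[li])) next
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 4L)
      stop(sprintf("%s line %d: malformed PAS line", basename(path), li))
    k <- suppressWarnings(as.integer(f[1L]))
    if (is.na(k) || k < 1L || k > n_sentences)
      stop(sprintf("%s line %d: sentence index out of range", basename(path), li))
    out[[k]] <- rbind(out[[k]], f[2:4])
  }
  out
}
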