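#' Read an annotated corpus from JSON lines
#'
#' One document per line:
#' `{"doc_id": str, "lang": str, "sentences": [[token,...],...],
#'   "terms": [{"sent": int, "start": int, "end": int, "cat": str},...]}`.
#' Token spans are 0-based, half-open: a term occupies tokens
#' `start .. end-1` of sentence `sent`. Categories outside
#' `{problem, treatment, test, other}` are warned about and mapped to
#' `"other"`; spans that leave their sentence are an error naming the
#' offending document.
#'
#' @param path path to a UTF-8 JSONL file.
#' @param language ISO 639-1 code of the corpus language.
#' @return an object of class `bilex_corpus`: a list with `language` and
#'   `documents`, each document a list of `doc_id`, `sentences` (list of
#'   character token vectors) and `terms` (data frame with columns
#'   `sent`, `start`, `end`, `cat`).
#' @export
read_corpus <- function(path, language) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- lapply(lines, function(ln) {
    d <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    sentences <- lapply(d$sentences, function(s) as.character(unlist(s)))
    terms <- parse_term_records(d$terms, sentences, d$doc_id)
    list(doc_id = as.character(d$doc_id), sentences = sentences, terms = terms)
  })
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ", ids[duplicated(ids)][1])
  }
  new_corpus(language, docs)
}

TERM_CATEGORIES <- c("problem", "treatment", "test", "other")

parse_term_records <- function(terms, sentences, doc_id) {
  if (is.null(terms) || length(terms) == 0L) {
    return(data.frame(sent = integer(), start = integer(), end = integer(),
                      cat = character(), stringsAsFactors = FALSE))
  }
  sent <- vapply(terms, function(t) as.integer(t$sent), integer(1))
  start <- vapply(terms, function(t) as.integer(t$start), integer(1))
  end <- vapply(terms, function(t) as.integer(t$end), integer(1))
  cat <- vapply(terms, function(t) {
    if (is.null(t$cat)) "other" else as.character(t$cat)
  }, character(1))
  bad_cat <- !(cat %in% TERM_CATEGORIES)
  if (any(bad_cat)) {
    warning("document ", doc_id, ": unknown term category ",
            paste(unique(cat[bad_cat]), collapse = ", "),
            " mapped to \"other\"")
    cat[bad_cat] <- "other"
  }
  n_sent <- length(sentences)
  ok_sent <- sent >= 0L & sent < n_sent
  if (!all(ok_sent)) {
    stop("document ", doc_id, ": term refers to sentence ",
         sent[!ok_sent][1], " outside 0..", n_sent - 1L)
  }
  slen <- vapply(sentences, length, integer(1))
  bad <- start < 0L | end > slen[sent + 1L] | start >= end
  if (any(bad)) {
    stop("document ", doc_id, ", sentence ", sent[bad][1],
         ": term span [", start[bad][1], ",", end[bad][1],
         ") outside token range 0..", slen[sent[bad][1] + 1L])
  }
  data.frame(sent = sent, start = start, end = end, cat = cat,
             stringsAsFactors = FALSE)
}

new_corpus <- function(language, documents) {
  structure(list(language = language, documents = documents),
            class = "bilex_corpus")
}

#' @export
print.bilex_corpus <- function(x, ...) {
  n_terms <- sum(vapply(x$documents, function(d) nrow(d$terms), integer(1)))
  cat("<bilex_corpus>", x$language, "-", length(x$documents),
      "documents,", n_terms, "term occurrences\n")
  invisible(x)
}

#' Write an annotated corpus as JSON lines
#'
#' Inverse of [read_corpus()]; emits the same canonical JSONL dialect so
#' `write_corpus(read_corpus(x))` round-trips byte for byte on canonical
#' files.
#'
#' @param corpus a `bilex_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "bilex_corpus"))
  lines <- vapply(corpus$documents, function(d) {
    terms <- lapply(seq_len(nrow(d$terms)), function(i) {
      list(sent = d$terms$sent[i], start = d$terms$start[i],
           end = d$terms$end[i], cat = d$terms$cat[i])
    })
    jsonlite::toJSON(
      list(doc_id = d$doc_id, lang = corpus$language,
           sentences = d$sentences, terms = terms),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a seed or gold lexicon from TSV
#'
#' Two tab-separated columns, source term then target term, words
#' space-separated within a column. Lines starting with `#` are comments; a
#' leading `source_term<TAB>target_term` header is recognized and skipped.
#' Blank lines are skipped with a warning. The i-th data line defines
#' dimension i-1 of the shared context-vector space.
#'
#' @param path TSV file path.
#' @return a `seed_lexicon`: data frame with character columns `source` and
#'   `target` holding canonical term keys, one row per seed pair, row order =
#'   dimension order.
#' @export
read_seed_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) && grepl("^source_term\ttarget_term\\s*$", lines[1]))
    lines <- lines[-1]
  blank <- !nzchar(trimws(lines))
  if (any(blank)) {
    warning("skipping ", sum(blank), " blank line(s) in ", path)
    lines <- lines[!blank]
  }
  pairs <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(pairs, length, integer(1)) != 2L
  if (any(bad)) stop("malformed lexicon line (need 2 tab-separated columns): ",
                     lines[bad][1])
  src <- vapply(pairs, function(p) term_key(strsplit(trimws(p[1]), "\\s+")[[1]]),
                character(1))
  tgt <- vapply(pairs, function(p) term_key(strsplit(trimws(p[2]), "\\s+")[[1]]),
                character(1))
  key <- paste(src, tgt, sep = "\t")
  if (anyDuplicated(key)) stop("duplicate seed pair: ", key[duplicated(key)][1])
  seed_lexicon(src, tgt)
}

#' Construct a seed lexicon from term keys
#'
#' @param source,target character vectors of canonical term keys, equal
#'   length, pair i defining dimension i-1.
#' @return a `seed_lexicon` data frame.
#' @export
seed_lexicon <- function(source, target) {
  stopifnot(length(source) == length(target))
  structure(data.frame(source = source, target = target,
                       stringsAsFactors = FALSE),
            class = c("seed_lexicon", "data.frame"))
}

#' Read a gold lexicon from TSV
#'
#' Same file dialect as [read_seed_lexicon()] but repeated source terms are
#' allowed: each source term maps to the set of all its listed translations.
#'
#' @inheritParams read_seed_lexicon
#' @return named list: source term key -> character vector of acceptable
#'   target term keys.
#' @export
read_gold_lexicon <- function(path) {
  lex <- suppressWarnings(try(read_seed_lexicon(path), silent = TRUE))
  if (inherits(lex, "try-error")) {
    # duplicates are legal in a gold file: reparse without the pair check
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) && grepl("^source_term\tgold", lines[1])) lines <- lines[-1]
    pairs <- strsplit(lines, "\t", fixed = TRUE)
    src <- vapply(pairs, function(p) term_key(strsplit(trimws(p[1]), "\\s+")[[1]]),
                  character(1))
    tgt <- vapply(pairs, function(p) term_key(strsplit(trimws(p[2]), "\\s+")[[1]]),
                  character(1))
    lex <- data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
  }
  split(lex$target, lex$source)
}

#' Build a term vocabulary from an annotated corpus
#'
#' Every term occurrence is assigned to one canonical term type
#' (case-folded surface words); occurrences and frequencies are collected
#' per type.
#'
#' @param corpus a `bilex_corpus`.
#' @return a `bilex_vocab`: list with `language`, `terms` (character keys),
#'   `freq` (named integer, sums to the total occurrence count),
#'   `nwords` (named integer) and `occurrences` (data frame with columns
#'   `term`, `doc`, `sent`, `start`, `end`, `cat`; `doc` is the 1-based
#'   document index).
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(inherits(corpus, "bilex_corpus"))
  occ <- lapply(seq_along(corpus$documents), function(di) {
    d <- corpus$documents[[di]]
    t <- d$terms
    if (nrow(t) == 0L) return(NULL)
    key <- vapply(seq_len(nrow(t)), function(i) {
      term_key(d$sentences[[t$sent[i] + 1L]][(t$start[i] + 1L):t$end[i]])
    }, character(1))
    data.frame(term = key, doc = di, sent = t$sent, start = t$start,
               end = t$end, cat = t$cat, stringsAsFactors = FALSE)
  })
  occ <- occ[!vapply(occ, is.null, logical(1))]
  occ <- if (length(occ)) {
    do.call(rbind, c(occ, list(make.row.names = FALSE)))
  } else {
    data.frame(term = character(), doc = integer(), sent = integer(),
               start = integer(), end = integer(), cat = character(),
               stringsAsFactors = FALSE)
  }
  freq <- table(occ$term)
  terms <- sort(names(freq))
  freq <- stats::setNames(as.integer(freq[terms]), terms)
  nwords <- vapply(terms, function(k) length(term_words(k)), integer(1))
  structure(list(language = corpus$language, terms = terms, freq = freq,
                 nwords = stats::setNames(nwords, terms), occurrences = occ),
            class = "bilex_vocab")
}

#' @export
print.bilex_vocab <- function(x, ...) {
  cat("<bilex_vocab>", x$language, "-", length(x$terms), "term types,",
      nrow(x$occurrences), "occurrences\n")
  invisible(x)
}

#' Build an order-insensitive word-set index over a vocabulary
#'
#' Maps each unordered word set to the terms of the vocabulary whose word
#' set (duplicated words collapsed) equals it. Used by the multi-word-term
#' aligner to test whether a word combination surfaces as a real term in the
#' target corpus.
#'
#' @param vocabulary a `bilex_vocab` built from the target corpus.
#' @return a `term_word_index`: named list, canonical sorted word-set key ->
#'   character vector of term keys.
#' @export
build_word_index <- function(vocabulary) {
  stopifnot(inherits(vocabulary, "bilex_vocab"))
  keys <- vapply(vocabulary$terms,
                 function(k) word_set_key(term_words(k)), character(1))
  structure(split(vocabulary$terms, keys), class = "term_word_index")
}

#' Look up terms by unordered word set
#'
#' @param index a `term_word_index`.
#' @param words character vector of words (order and duplication ignored).
#' @return character vector of matching term keys (possibly empty).
#' @export
lookup_word_set <- function(index, words) {
  stopifnot(inherits(index, "term_word_index"))
  hit <- index[[word_set_key(words)]]
  if (is.null(hit)) character(0) else hit
}
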