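# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Write a JSONL corpus file from a list of documents and read it back.
# Each document: list(doc_id=, sentences=list(character vectors),
# terms=list(list(sent=,start=,end=,cat=), ...))
jsonl_corpus <- function(docs, lang = "en", path = tempfile(fileext = ".jsonl")) {
  lines <- vapply(docs, function(d) {
    jsonlite::toJSON(list(doc_id = d$doc_id, lang = lang,
                          sentences = d$sentences,
                          terms = if (is.null(d$terms)) list() else d$terms),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  read_corpus(path, lang)
}

doc <- function(doc_id, sentences, terms = list()) {
  list(doc_id = doc_id, sentences = sentences, terms = terms)
}

span <- function(sent, start, end, cat = "problem") {
  list(sent = sent, start = start, end = end, cat = cat)
}

# A corpus from one tagged sentence per element: each sentence is a
# character vector of tokens; `spans` a list of c(start, end) per sentence
# index (1-based list position -> 0-based sent field).
one_doc_corpus <- function(sentences, spans_per_sentence, lang = "en") {
  terms <- list()
  for (si in seq_along(spans_per_sentence)) {
    for (sp in spans_per_sentence[[si]]) {
      terms[[length(terms) + 1L]] <- span(si - 1L, sp[1], sp[2])
    }
  }
  jsonl_corpus(list(doc(doc_id = "d1", sentences = sentences, terms = terms)),
               lang = lang)
}

# Sentence where every token is its own annotated single-word term.
all_token_terms <- function(tokens_per_sentence) {
  lapply(tokens_per_sentence, function(n) {
    lapply(seq_len(n) - 1L, function(s) c(s, s + 1L))
  })
}

# Directly assemble a cooc_graph (white-box, for LP unit tests): edges is a
# data frame with columns i, j, w (vertex names); seeds a named list
# vertex -> integer dims.
toy_graph <- function(vertices, edges, seeds, n_dims = length(seeds)) {
  nv <- length(vertices)
  W <- Matrix::sparseMatrix(
    i = c(match(edges$i, vertices), match(edges$j, vertices)),
    j = c(match(edges$j, vertices), match(edges$i, vertices)),
    x = rep(edges$w, 2), dims = c(nv, nv),
    dimnames = list(vertices, vertices))
  structure(list(vertices = vertices, W = W, seed_dims = seeds,
                 n_dims = n_dims,
                 freq = stats::setNames(rep(1L, nv), vertices)),
            class = "cooc_graph")
}

# Random connected weighted graph: random spanning tree plus
# Erdos-Renyi extra edges, <= 5 seed vertices each owning one dimension.
random_cooc_graph <- function(nv, nseed, p_extra = 0.3) {
  W <- matrix(0, nv, nv)
  for (v in seq_len(nv)[-1]) {
    u <- sample.int(v - 1L, 1L)
    W[u, v] <- W[v, u] <- stats::runif(1, 0.2, 1)
  }
  extra <- which(upper.tri(W) & W == 0 & stats::runif(nv * nv) < p_extra)
  W[extra] <- stats::runif(length(extra), 0.2, 1)
  W <- pmax(W, t(W))
  verts <- sprintf("v%02d", seq_len(nv))
  dimnames(W) <- list(verts, verts)
  seeds <- sample.int(nv, nseed)
  structure(list(vertices = verts, W = Matrix::Matrix(W, sparse = TRUE),
                 seed_dims = stats::setNames(as.list(seq_len(nseed)),
                                             verts[seeds]),
                 n_dims = nseed,
                 freq = stats::setNames(rep(1L, nv), verts)),
            class = "cooc_graph")
}

# Small synthetic worlds used by several files.
small_synth <- function(rng_seed = 1L, noise = 0, n_seed = 50L, n_swt = 30L,
                        mwt_counts = c(), docs = 15L,
                        mwt_occ = 3L) {
  generate_comparable_corpora(synth_config(
    n_seed_pairs = n_seed, n_swt_pairs = n_swt, mwt_pair_counts = mwt_counts,
    docs_per_language = docs,
    sentences_per_doc = c(source = 10L, target = 20L),
    terms_per_sentence = c(source = 6L, target = 3L),
    noise_rate = c(source = noise, target = noise),
    mwt_term_occurrences = mwt_occ, rng_seed = rng_seed))
}
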