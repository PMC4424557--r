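#' Split multi-word term occurrences into single-word vertices
#'
#' For the multi-word-term aligner the source graph must contain each
#' component word as its own vertex. This transform rewrites every
#' annotated occurrence spanning more than one token into one single-token
#' occurrence per component word (same sentence, same category), leaving
#' single-word occurrences untouched.
#'
#' @param corpus a `bilex_corpus`.
#' @return a `bilex_corpus` with only single-token term occurrences.
#' @export
explode_mwt <- function(corpus) {
  stopifnot(inherits(corpus, "bilex_corpus"))
  docs <- lapply(corpus$documents, function(d) {
    t <- d$terms
    if (nrow(t) == 0L) return(d)
    pieces <- lapply(seq_len(nrow(t)), function(i) {
      pos <- t$start[i]:(t$end[i] - 1L)
      data.frame(sent = t$sent[i], start = pos, end = pos + 1L,
                 cat = t$cat[i], stringsAsFactors = FALSE)
    })
    d$terms <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
    d
  })
  new_corpus(corpus$language, docs)
}

#' Step 1: translation-candidate words for one component
#'
#' Takes the top-K ranked target terms for a single-word component vertex
#' and flattens them to their component words; each word's similarity is
#' the maximum ranking score among the top-K terms containing it.
#'
#' @param component single-word source term key (a source-graph vertex).
#' @param model an `lp_model`.
#' @param K candidate-list cutoff (default 100, the standard setting).
#' @return named numeric vector: candidate word -> similarity, sorted
#'   descending. `K = 0` gives an empty vector.
#' @export
component_candidate_words <- function(component, model, K = 100L) {
  stopifnot(K >= 0)
  if (K == 0L) return(stats::setNames(numeric(0), character(0)))
  ranking <- rank_lp(model, component)
  top <- utils::head(ranking, K)
  sims <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(top))) {
    for (w in term_words(top$candidate[i])) {
      prev <- get0(w, envir = sims, ifnotfound = -Inf)
      if (top$score[i] > prev) assign(w, top$score[i], envir = sims)
    }
  }
  out <- unlist(as.list(sims))
  if (is.null(out)) return(stats::setNames(numeric(0), character(0)))
  sort(out, decreasing = TRUE)
}

#' Step 2: intersect per-component candidate word sets
#'
#' @param candidate_word_sets list (length >= 2) of named numeric vectors
#'   from [component_candidate_words()], one per component.
#' @return list with `words` (the intersection, possibly empty) and `sims`
#'   (words x components matrix of per-component similarities).
#' @export
intersect_candidates <- function(candidate_word_sets) {
  stopifnot(is.list(candidate_word_sets), length(candidate_word_sets) >= 2L)
  words <- Reduce(intersect, lapply(candidate_word_sets, names))
  sims <- vapply(candidate_word_sets, function(s) {
    unname(s[words])
  }, numeric(length(words)))
  sims <- matrix(sims, nrow = length(words),
                 dimnames = list(words, names(candidate_word_sets)))
  list(words = words, sims = sims)
}

#' Step 3: enumerate word combinations that surface as target terms
#'
#' Enumerates every unordered subset of 1..`n_max` words from the
#' intersection set and keeps exactly those whose word set equals the word
#' set of at least one target-corpus term (via the [build_word_index()]
#' index); all other subsets are discarded.
#'
#' @param intersection character vector of candidate words (size q).
#' @param n_max largest subset size to try; combinations longer than the
#'   source term are unreachable by construction, so callers default this
#'   to the source word count m.
#' @param index a `term_word_index` over the target vocabulary.
#' @return list of survivors, each a list with `words` (the subset) and
#'   `terms` (matched term keys); attribute `examined` counts enumerated
#'   subsets, which equals `sum(choose(q, 1:n_max))`.
#' @export
enumerate_combinations <- function(intersection, n_max, index) {
  stopifnot(n_max >= 1)
  q <- length(intersection)
  out <- list()
  examined <- 0L
  for (j in seq_len(min(n_max, q))) {
    subs <- utils::combn(intersection, j, simplify = FALSE)
    examined <- examined + length(subs)
    for (s in subs) {
      hits <- lookup_word_set(index, s)
      if (length(hits)) out[[length(out) + 1L]] <- list(words = s, terms = hits)
    }
  }
  # sizes j > q contribute choose(q, j) = 0 enumerations
  attr(out, "examined") <- examined
  out
}

#' Step 4: plausibility of one combination
#'
#' Default (`mode = "pairs-mean"`): the mean of sim(component, word) over
#' all (component, candidate word) pairs, where a word absent from a
#' component's candidate list contributes 0. Alternative
#' (`mode = "best-match"`): the mean over components of each component's
#' best similarity to any word of the combination.
#'
#' @param words character vector, the combination's word subset.
#' @param component_sims words x components similarity matrix (rows may be
#'   a superset of `words`; missing rows count as 0).
#' @param mode `"pairs-mean"` (default) or `"best-match"`.
#' @return plausibility in `[0, 1]`.
#' @export
score_combination <- function(words, component_sims,
                              mode = c("pairs-mean", "best-match")) {
  mode <- match.arg(mode)
  if (!length(words)) stop("empty combination")
  S <- matrix(0, nrow = length(words), ncol = ncol(component_sims),
              dimnames = list(words, colnames(component_sims)))
  present <- intersect(words, rownames(component_sims))
  S[present, ] <- component_sims[present, , drop = FALSE]
  S[is.na(S)] <- 0
  if (mode == "pairs-mean") mean(S) else mean(apply(S, 2, max))
}

#' Align a multi-word term (Steps 1-4)
#'
#' Runs the full compositional alignment for one source MWT: per-component
#' candidate generation on the exploded source graph, candidate-word
#' intersection, subset-to-target-term matching, and plausibility ranking.
#' Ties break toward the shorter target term, then lexicographically.
#'
#' @param mwt source MWT term key (m >= 2 words).
#' @param model an `lp_model` fitted on corpora whose source side has the
#'   component words as vertices (see [explode_mwt()]).
#' @param index a `term_word_index` over the target vocabulary.
#' @param K per-component candidate cutoff (default 100).
#' @param n_max maximum target length; `NULL` (default) uses m, the source
#'   word count.
#' @param score_mode passed to [score_combination()].
#' @param on_missing what to do when a component word is not a source-graph
#'   vertex: `"partial"` (default) drops it and proceeds if at least two
#'   components remain, recording the degradation in the `dropped`
#'   attribute; `"error"` fails.
#' @return a `candidate_ranking` over matched target terms (possibly
#'   0-row), with attributes `examined`, `survivors` and `dropped`.
#' @export
align_mwt <- function(mwt, model, index, K = 100L, n_max = NULL,
                      score_mode = "pairs-mean",
                      on_missing = c("partial", "error")) {
  on_missing <- match.arg(on_missing)
  comps <- term_words(mwt)
  if (length(comps) < 2L) stop("not an MWT (need >= 2 component words): ", mwt)
  present <- comps %in% rownames(model$source$labels)
  if (any(!present)) {
    if (on_missing == "error" || sum(present) < 2L) {
      stop("fewer than 2 resolvable components for ", mwt, "; missing: ",
           paste(comps[!present], collapse = ", "))
    }
    dropped <- comps[!present]
    comps <- comps[present]
  } else dropped <- character(0)
  if (is.null(n_max)) n_max <- length(term_words(mwt))

  sets <- lapply(comps, component_candidate_words, model = model, K = K)
  names(sets) <- comps
  inter <- intersect_candidates(sets)

  if (!length(inter$words)) {
    ranking <- make_ranking(stats::setNames(numeric(0), character(0)))
  } else {
    combos <- enumerate_combinations(inter$words, n_max, index)
    scores <- new.env(parent = emptyenv())
    for (cb in combos) {
      s <- score_combination(cb$words, inter$sims, mode = score_mode)
      for (tm in cb$terms) {
        prev <- get0(tm, envir = scores, ifnotfound = -Inf)
        if (s > prev) assign(tm, s, envir = scores)
      }
    }
    sc <- unlist(as.list(scores))
    if (is.null(sc)) sc <- stats::setNames(numeric(0), character(0))
    ranking <- rank_mwt_candidates(sc)
    attr(ranking, "examined") <- attr(combos, "examined")
  }
  attr(ranking, "survivors") <- nrow(ranking)
  attr(ranking, "dropped") <- dropped
  ranking
}

# ranking with the MWT tie-break: score desc, shorter term first, then lex
rank_mwt_candidates <- function(scores) {
  cand <- names(scores)
  len <- vapply(cand, function(k) length(term_words(k)), integer(1))
  ord <- order(-scores, len, cand, method = "radix")
  structure(data.frame(candidate = cand[ord],
                       score = as.numeric(scores[ord]),
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("candidate_ranking", "data.frame"))
}
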