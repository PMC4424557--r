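#' Context window policy
#'
#' The context of a term occurrence is the nearest seed occurrence strictly
#' to its left and the nearest strictly to its right — a deliberately narrow
#' window that is robust to the large sentence-length asymmetry between the
#' two corpora. Distances are token distances from the occurrence's span
#' boundary.
#'
#' @param sentence_bounded if `TRUE` (default) neighbours are searched only
#'   within the same sentence.
#' @param max_token_distance optional cap (>= 1) on the token distance to a
#'   neighbouring seed; `NULL` means unbounded.
#' @return a `window_policy` list.
#' @export
window_policy <- function(sentence_bounded = TRUE, max_token_distance = NULL) {
  if (!is.null(max_token_distance)) {
    stopifnot(is.numeric(max_token_distance), max_token_distance >= 1)
    max_token_distance <- as.integer(max_token_distance)
  }
  structure(list(mode = "nearest-seed-each-side",
                 sentence_bounded = isTRUE(sentence_bounded),
                 max_token_distance = max_token_distance),
            class = "window_policy")
}

#' Extract seed-pair indexed context vectors
#'
#' Builds, for every term type in the vocabulary, a sparse nonnegative
#' vector over the seed-pair dimensions: for each occurrence of the term,
#' the nearest seed occurrence strictly to its left and the nearest strictly
#' to its right each add +1 to the dimension(s) of the seed pair(s) whose
#' language-appropriate side equals that seed's term type. A seed term
#' appearing in k pairs credits all k dimensions. A side with no seed
#' contributes nothing. Occurrences of seed terms themselves also receive
#' vectors (needed for graph edge weights).
#'
#' Because dimensions are indexed by seed *pair*, vectors from the source
#' and target corpora live in the same space and cross-language cosine is
#' well defined.
#'
#' @param corpus a `bilex_corpus`.
#' @param lexicon a `seed_lexicon`; its row order defines the dimensions.
#' @param policy a [window_policy()].
#' @param vocabulary optional precomputed [build_vocabulary()] result.
#' @param side which lexicon column names this corpus's seed terms:
#'   `"auto"` (default; `"en"` is taken as the target side), `"source"` or
#'   `"target"`.
#' @return a sparse `Matrix::dgCMatrix` (terms x seed pairs) with term keys
#'   as row names; all-zero rows are kept.
#' @export
extract_context_vectors <- function(corpus, lexicon,
                                    policy = window_policy(),
                                    vocabulary = NULL,
                                    side = c("auto", "source", "target")) {
  stopifnot(inherits(corpus, "bilex_corpus"), inherits(lexicon, "seed_lexicon"))
  side <- match.arg(side)
  if (nrow(lexicon) == 0L) stop("empty seed lexicon")
  if (is.null(vocabulary)) vocabulary <- build_vocabulary(corpus)
  seed_terms <- switch(side,
    auto = lexicon_side(lexicon, corpus$language),
    source = lexicon$source,
    target = lexicon$target)
  # term key -> integer dims (a term on one side of k pairs owns k dims)
  seed_dims <- split(seq_len(nrow(lexicon)), seed_terms)

  n <- nrow(lexicon)
  terms <- vocabulary$terms
  occ <- vocabulary$occurrences
  ti <- integer(0); di <- integer(0)  # triplet accumulators (term, dim)

  if (nrow(occ)) {
    is_seed <- occ$term %in% names(seed_dims)
    grp <- interaction(occ$doc, occ$sent, drop = TRUE)
    for (g in split(seq_len(nrow(occ)), grp)) {
      seeds_g <- g[is_seed[g]]
      if (!length(seeds_g)) next
      s_start <- occ$start[seeds_g]; s_end <- occ$end[seeds_g]
      for (i in g) {
        # left: seed span entirely before this occurrence's start
        dl <- occ$start[i] - s_end
        left <- which(dl >= 0 & seeds_g != i)
        # right: seed span entirely after this occurrence's end
        dr <- s_start - occ$end[i]
        right <- which(dr >= 0 & seeds_g != i)
        if (!is.null(policy$max_token_distance)) {
          left <- left[dl[left] <= policy$max_token_distance]
          right <- right[dr[right] <= policy$max_token_distance]
        }
        for (sel in list(
          if (length(left)) seeds_g[left[which.min(dl[left])]],
          if (length(right)) seeds_g[right[which.min(dr[right])]])) {
          if (is.null(sel)) next
          dims <- seed_dims[[occ$term[sel]]]
          ti <- c(ti, rep.int(match(occ$term[i], terms), length(dims)))
          di <- c(di, dims)
        }
      }
    }
  }
  Matrix::sparseMatrix(i = ti, j = di, x = rep.int(1, length(ti)),
                       dims = c(length(terms), n),
                       dimnames = list(terms, NULL))
}

lexicon_side <- function(lexicon, language) {
  # the source language is the one the lexicon's source column was read in;
  # callers tag corpora with matching codes via the pipeline config
  side <- attr(lexicon, "languages")
  if (!is.null(side) && language %in% names(side)) {
    return(lexicon[[side[[language]]]])
  }
  # default convention: "en" is the target side, anything else the source
  if (identical(language, "en")) lexicon$target else lexicon$source
}

#' Cosine similarity of two context vectors
#'
#' Standard cosine; defined as 0 when either vector is all-zero. Vectors
#' must share the seed-pair dimension count.
#'
#' @param f_i,f_j numeric (possibly sparse) vectors of equal length.
#' @return similarity in `[0, 1]` for nonnegative inputs.
#' @export
cosine <- function(f_i, f_j) {
  f_i <- as.numeric(f_i); f_j <- as.numeric(f_j)
  if (length(f_i) != length(f_j)) {
    stop("dimension mismatch: ", length(f_i), " vs ", length(f_j))
  }
  ni <- sqrt(sum(f_i^2)); nj <- sqrt(sum(f_j^2))
  if (ni == 0 || nj == 0) return(0)
  sum(f_i * f_j) / (ni * nj)
}

# cosine of one vector against every row of a (sparse) matrix; zero rows -> 0
cosine_rows <- function(v, M) {
  v <- as.numeric(v)
  nv <- sqrt(sum(v^2))
  rn <- sqrt(Matrix::rowSums(M^2))
  s <- as.numeric(M %*% v)
  out <- ifelse(nv == 0 | rn == 0, 0, s / (nv * rn))
  stats::setNames(out, rownames(M))
}

#' Rank translation candidates by context similarity (baseline)
#'
#' Orders target-language terms by the cosine of their context vectors with
#' the test term's vector. Ties break deterministically: higher corpus
#' frequency first, then lexicographically on the term key.
#'
#' @param test_vector numeric vector (one row of the source matrix).
#' @param target_vectors sparse matrix of target context vectors with term
#'   keys as row names.
#' @param target_freq named integer vector of target corpus frequencies
#'   (missing terms count as 0).
#' @return a `candidate_ranking` data frame with columns `candidate`,
#'   `score`, `rank`.
#' @export
rank_baseline <- function(test_vector, target_vectors, target_freq = NULL) {
  if (is.null(rownames(target_vectors)) || nrow(target_vectors) == 0L) {
    stop("empty candidate set")
  }
  scores <- cosine_rows(test_vector, target_vectors)
  make_ranking(scores, target_freq)
}

make_ranking <- function(scores, freq = NULL) {
  cand <- names(scores)
  f <- if (is.null(freq)) rep.int(0L, length(cand)) else {
    ifelse(cand %in% names(freq), freq[cand], 0L)
  }
  ord <- order(-scores, -f, cand, method = "radix")
  structure(data.frame(candidate = cand[ord],
                       score = as.numeric(scores[ord]),
                       rank = seq_along(ord),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("candidate_ranking", "data.frame"))
}
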