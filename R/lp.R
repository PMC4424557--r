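#' Build the monolingual co-occurrence graph
#'
#' Vertices are the term types of one language. An edge joins two terms iff
#' they co-occur at least once within the same sentence; its weight is the
#' cosine of their context vectors (default) or the raw co-occurrence count
#' (`edge_weight = "freq"`). Zero-weight edges are dropped; the graph is
#' undirected with no self-loops. Seed vertices carry the dimension(s) of
#' the seed pair(s) they belong to.
#'
#' @param vocabulary a `bilex_vocab` for the corpus.
#' @param context_vectors sparse matrix from [extract_context_vectors()],
#'   rows aligned with `vocabulary$terms`.
#' @param corpus the `bilex_corpus` the vocabulary came from.
#' @param lexicon a `seed_lexicon`.
#' @param edge_weight `"cosine"` (default, the better-performing choice) or
#'   `"freq"`.
#' @param side see [extract_context_vectors()].
#' @return a `cooc_graph`: list with `vertices`, sparse symmetric weight
#'   matrix `W`, `seed_dims` (named list vertex -> integer dims), `n_dims`,
#'   and `freq`.
#' @export
build_graph <- function(vocabulary, context_vectors, corpus, lexicon,
                        edge_weight = c("cosine", "freq"),
                        side = c("auto", "source", "target")) {
  stopifnot(inherits(vocabulary, "bilex_vocab"))
  edge_weight <- match.arg(edge_weight)
  side <- match.arg(side)
  terms <- vocabulary$terms
  if (!length(terms)) stop("empty vocabulary")
  nt <- length(terms)

  occ <- vocabulary$occurrences
  # sentence incidence: term x (doc,sent) cell, then co-occurrence counts
  cell <- interaction(occ$doc, occ$sent, drop = TRUE)
  A <- Matrix::sparseMatrix(i = match(occ$term, terms),
                            j = as.integer(cell),
                            x = 1,
                            dims = c(nt, nlevels(cell)),
                            dimnames = list(terms, NULL))
  C <- Matrix::tcrossprod(A)        # co-occurrence counts (incl. self)
  Matrix::diag(C) <- 0
  C <- Matrix::drop0(C)

  if (edge_weight == "cosine") {
    idx <- Matrix::which(C != 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (nrow(idx)) {
      rn <- sqrt(Matrix::rowSums(context_vectors^2))
      Vn <- context_vectors / ifelse(rn > 0, rn, 1)
      w <- Matrix::rowSums(Vn[idx[, 1], , drop = FALSE] *
                             Vn[idx[, 2], , drop = FALSE])
      keep <- w > 0
      W <- Matrix::sparseMatrix(i = idx[keep, 1], j = idx[keep, 2],
                                x = w[keep], dims = c(nt, nt),
                                dimnames = list(terms, terms),
                                symmetric = TRUE)
      W <- methods::as(W, "generalMatrix")
    } else {
      W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nt, nt), dimnames = list(terms, terms))
    }
  } else {
    W <- C
  }

  seed_terms <- switch(side,
    auto = lexicon_side(lexicon, corpus$language),
    source = lexicon$source,
    target = lexicon$target)
  dims_by_term <- split(seq_len(nrow(lexicon)), seed_terms)
  seed_dims <- dims_by_term[names(dims_by_term) %in% terms]

  structure(list(vertices = terms, W = W, seed_dims = seed_dims,
                 n_dims = nrow(lexicon), freq = vocabulary$freq),
            class = "cooc_graph")
}

#' @export
print.cooc_graph <- function(x, ...) {
  ne <- Matrix::nnzero(x$W) / 2
  cat("<cooc_graph>", length(x$vertices), "vertices,", ne, "edges,",
      length(x$seed_dims), "seed vertices,", x$n_dims, "label dimensions\n")
  invisible(x)
}

#' Initialize the label matrix
#'
#' Seed vertices get a one-hot label on their own seed-pair dimension;
#' every other vertex gets the uniform distribution `u(z) = 1/n`. A seed
#' term that belongs to several seed pairs is a single vertex clamped to
#' the uniform mixture of its own dimensions.
#'
#' @param graph a `cooc_graph` with at least one seed vertex.
#' @return a dense numeric matrix, vertices x dimensions, rows on the
#'   probability simplex; attribute `iterations` = 0.
#' @export
init_labels <- function(graph) {
  stopifnot(inherits(graph, "cooc_graph"))
  if (!length(graph$seed_dims)) stop("empty seed set: no seed vertex in graph")
  nv <- length(graph$vertices); n <- graph$n_dims
  Q <- matrix(1 / n, nrow = nv, ncol = n,
              dimnames = list(graph$vertices, NULL))
  for (s in names(graph$seed_dims)) {
    dims <- graph$seed_dims[[s]]
    row <- numeric(n)
    row[dims] <- 1 / length(dims)
    Q[s, ] <- row
  }
  attr(Q, "iterations") <- 0L
  Q
}

#' Propagate labels through the graph
#'
#' Synchronous (Jacobi-style) iteration: each cycle replaces every non-seed
#' vertex's label with the weight-normalized average of its neighbours'
#' previous-cycle labels; seed labels are re-clamped to their initial values
#' every cycle. A vertex with no neighbours (or all-zero incident weight)
#' keeps its previous label. The default of 10 cycles follows the original
#' experimental setting; set `tol` to stop early once the max-abs change
#' falls below it.
#'
#' @param graph a `cooc_graph`.
#' @param labels label matrix from [init_labels()].
#' @param iterations number of cycles (default 10).
#' @param tol optional early-stopping threshold on the max-abs label change;
#'   `NULL` (default) runs all `iterations` cycles.
#' @return the updated label matrix; attribute `iterations` counts total
#'   cycles applied.
#' @export
propagate <- function(graph, labels, iterations = 10L, tol = NULL) {
  stopifnot(inherits(graph, "cooc_graph"))
  if (is.null(attr(labels, "iterations"))) {
    stop("labels must come from init_labels()/propagate()")
  }
  W <- graph$W
  deg <- Matrix::rowSums(W)
  upd <- deg > 0
  seeds <- names(graph$seed_dims)
  is_seed <- rownames(labels) %in% seeds
  Q0 <- labels[is_seed, , drop = FALSE]
  Q <- labels
  done <- 0L
  for (m in seq_len(iterations)) {
    Qn <- Q
    prop <- as.matrix(W %*% Q) / deg
    Qn[upd, ] <- prop[upd, , drop = FALSE]
    Qn[is_seed, ] <- Q0
    done <- done + 1L
    delta <- max(abs(Qn - Q))
    Q <- Qn
    if (!is.null(tol) && delta < tol) break
  }
  attr(Q, "iterations") <- attr(labels, "iterations") + done
  Q
}

#' Exact fixed point of clamped label propagation
#'
#' Independent oracle for [propagate()]: the iteration's fixed point is the
#' harmonic function on the graph with seed labels clamped, obtained by
#' solving one sparse linear system `(D - W)_uu q_u = W_us q_s` shared by
#' all label dimensions. Non-seed vertices in a connected component with no
#' seed (including isolated vertices) keep the uniform label, which is the
#' iteration's invariant value there.
#'
#' @param graph a `cooc_graph`.
#' @return a label matrix satisfying the update equation to residual
#'   < 1e-10.
#' @export
fixed_point_oracle <- function(graph) {
  Q <- init_labels(graph)
  seeds <- names(graph$seed_dims)
  is_seed <- rownames(Q) %in% seeds
  W <- graph$W
  deg <- Matrix::rowSums(W)

  # restrict to unlabeled vertices reachable from a seed through edges
  reach <- is_seed
  repeat {
    nxt <- reach | (as.numeric(W %*% reach) > 0)
    if (all(nxt == reach)) break
    reach <- nxt
  }
  u <- which(!is_seed & reach & deg > 0)
  if (length(u)) {
    s <- which(is_seed)
    L <- Matrix::Diagonal(x = deg[u]) - W[u, u, drop = FALSE]
    B <- W[u, s, drop = FALSE] %*% Q[s, , drop = FALSE]
    sol <- try(Matrix::solve(L, B), silent = TRUE)
    if (inherits(sol, "try-error")) {
      stop("singular clamped-harmonic system on component containing: ",
           rownames(Q)[u[1]])
    }
    Q[u, ] <- as.matrix(sol)
  }
  attr(Q, "iterations") <- NA_integer_
  Q
}

#' Fit label propagation on both language sides
#'
#' Convenience wrapper running vocabulary construction, context-vector
#' extraction, graph construction and propagation for the source and target
#' corpora, producing the model object consumed by [rank_lp()] and
#' [align_mwt()].
#'
#' @param source_corpus,target_corpus `bilex_corpus` objects.
#' @param lexicon a `seed_lexicon`.
#' @param policy a [window_policy()].
#' @param iterations propagation cycles (default 10).
#' @param edge_weight passed to [build_graph()].
#' @return an `lp_model`: list with per-side `graph`, `labels`, `vectors`,
#'   `vocab`, plus the `lexicon`.
#' @export
fit_lp <- function(source_corpus, target_corpus, lexicon,
                   policy = window_policy(), iterations = 10L,
                   edge_weight = "cosine") {
  fit_side <- function(corpus, side) {
    vocab <- build_vocabulary(corpus)
    vec <- extract_context_vectors(corpus, lexicon, policy, vocab, side = side)
    graph <- build_graph(vocab, vec, corpus, lexicon,
                         edge_weight = edge_weight, side = side)
    labels <- propagate(graph, init_labels(graph), iterations = iterations)
    list(vocab = vocab, vectors = vec, graph = graph, labels = labels)
  }
  structure(list(source = fit_side(source_corpus, "source"),
                 target = fit_side(target_corpus, "target"),
                 lexicon = lexicon),
            class = "lp_model")
}

#' @export
print.lp_model <- function(x, ...) {
  cat("<lp_model>\n  source: "); print(x$source$graph)
  cat("  target: "); print(x$target$graph)
  invisible(x)
}

#' Rank cross-language candidates by propagated labels
#'
#' Scores every target-language vertex by the cosine of its converged label
#' vector with the test term's, descending, with the same deterministic
#' tie-break as [rank_baseline()] (frequency, then lexicographic).
#'
#' @param model an `lp_model` from [fit_lp()].
#' @param test_term source-language term key; must be a source-graph vertex.
#' @param include_seeds keep target seed vertices among the candidates
#'   (default `TRUE`).
#' @return a `candidate_ranking` data frame.
#' @export
rank_lp <- function(model, test_term, include_seeds = TRUE) {
  stopifnot(inherits(model, "lp_model"))
  src <- model$source$labels
  if (!test_term %in% rownames(src)) {
    stop("test term not in source graph: ", test_term)
  }
  tgt <- model$target$labels
  if (!include_seeds) {
    keep <- !(rownames(tgt) %in% names(model$target$graph$seed_dims))
    tgt <- tgt[keep, , drop = FALSE]
  }
  if (!nrow(tgt)) stop("empty candidate set")
  scores <- cosine_rows(src[test_term, ], tgt)
  make_ranking(scores, model$target$vocab$freq)
}
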