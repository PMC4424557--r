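test_that("build_graph links same-sentence terms weighted by context cosine", {
  lex <- seed_lexicon(paste0("s", 1:3), paste0("e", 1:3))
  # a, b share a sentence and identical contexts; c never co-occurs with a
  corp <- one_doc_corpus(
    list(c("s1", "a", "s2", "b", "s1"), c("s3", "c", "s3")),
    all_token_terms(c(5, 3)), lang = "zh")
  vocab <- build_vocabulary(corp)
  V <- extract_context_vectors(corp, lex, vocabulary = vocab, side = "source")
  g <- build_graph(vocab, V, corp, lex, side = "source")
  expect_equal(g$W["a", "c"], 0)
  expect_gt(g$W["a", "b"], 0)
  expect_equal(g$W["a", "b"], cosine(V["a", ], V["b", ]))
  # undirected, no self-loops
  expect_equal(g$W, Matrix::t(g$W))
  expect_true(all(Matrix::diag(g$W) == 0))
  expect_error(build_graph(build_vocabulary(jsonl_corpus(list())), V, corp,
                           lex), "empty vocabulary")
})

test_that("graph edges equal a brute-force co-occurrence scan with cosines", {
  set.seed(21)
  lex <- seed_lexicon(paste0("s", 1:4), paste0("e", 1:4))
  toks <- sample(c(paste0("s", 1:4), letters[1:6]), 36, replace = TRUE)
  sents <- split(toks, rep(1:6, each = 6))
  corp <- one_doc_corpus(unname(sents), all_token_terms(rep(6, 6)),
                         lang = "zh")
  vocab <- build_vocabulary(corp)
  V <- extract_context_vectors(corp, lex, vocabulary = vocab, side = "source")
  g <- build_graph(vocab, V, corp, lex, side = "source")
  for (i in vocab$terms) for (j in vocab$terms) {
    if (i >= j) next
    cooc <- any(vapply(sents, function(s) i %in% s && j %in% s, logical(1)))
    w_expect <- if (cooc) cosine(V[i, ], V[j, ]) else 0
    expect_equal(g$W[i, j], w_expect, tolerance = 1e-12)
  }
  # frequency edge weights are the co-occurrence counts
  gf <- build_graph(vocab, V, corp, lex, edge_weight = "freq", side = "source")
  cnt_ab <- sum(vapply(sents, function(s) {
    sum(s == vocab$terms[1]) * sum(s == vocab$terms[2])
  }, numeric(1)))
  expect_equal(gf$W[vocab$terms[1], vocab$terms[2]], cnt_ab)
})

test_that("init_labels is one-hot on seeds, uniform elsewhere", {
  g <- toy_graph(c("x", "a", "b", "c", "d"),
                 data.frame(i = "x", j = c("a", "b", "c", "d"), w = 1),
                 seeds = list(a = 1L, b = 2L, c = 3L, d = 4L))
  Q <- init_labels(g)
  expect_equal(unname(Q["x", ]), rep(0.25, 4))
  expect_equal(unname(Q["c", ]), c(0, 0, 1, 0))
  g0 <- g; g0$seed_dims <- list()
  expect_error(init_labels(g0), "empty seed set")
  # a seed term owning two pairs is clamped to their uniform mixture
  g2 <- toy_graph(c("x", "a"), data.frame(i = "x", j = "a", w = 1),
                  seeds = list(a = c(1L, 3L)), n_dims = 3)
  expect_equal(unname(init_labels(g2)["a", ]), c(0.5, 0, 0.5))
})

test_that("one propagation cycle averages neighbours; seeds stay clamped", {
  g <- toy_graph(c("x", "a", "b"),
                 data.frame(i = "x", j = c("a", "b"), w = c(1, 1)),
                 seeds = list(a = 1L, b = 2L))
  Q1 <- propagate(g, init_labels(g), iterations = 1)
  expect_identical(unname(Q1["x", ]), c(0.5, 0.5))
  Q10 <- propagate(g, init_labels(g), iterations = 10)
  expect_identical(unname(Q10["a", ]), c(1, 0))  # bit-identical clamp
  expect_identical(unname(Q10["b", ]), c(0, 1))

  # isolated non-seed keeps the uniform label
  g2 <- toy_graph(c("x", "a", "b", "iso"),
                  data.frame(i = "x", j = c("a", "b"), w = 1),
                  seeds = list(a = 1L, b = 2L))
  Q <- propagate(g2, init_labels(g2), iterations = 10)
  expect_equal(unname(Q["iso", ]), c(0.5, 0.5))
  expect_error(propagate(g2, matrix(0.5, 4, 2)), "init_labels")
})

test_that("labels stay on the simplex through every cycle", {
  set.seed(31)
  for (rep in 1:5) {
    g <- random_cooc_graph(sample(6:20, 1), sample(2:5, 1))
    Q <- init_labels(g)
    for (m in 1:10) {
      Q <- propagate(g, Q, iterations = 1)
      expect_true(all(Q >= 0))
      expect_equal(unname(Matrix::rowSums(Q)), rep(1, nrow(Q)),
                   tolerance = 1e-9)
    }
  }
})

test_that("fixed_point_oracle solves the clamped-harmonic system", {
  # chain seed(dim1) - x - seed(dim2), equal weights -> x = (0.5, 0.5)
  g <- toy_graph(c("a", "x", "b"),
                 data.frame(i = c("a", "x"), j = c("x", "b"), w = 1),
                 seeds = list(a = 1L, b = 2L))
  expect_equal(unname(fixed_point_oracle(g)["x", ]), c(0.5, 0.5))

  # star with seed weights 1, 1, 2 -> (0.25, 0.25, 0.5)
  g2 <- toy_graph(c("x", "a", "b", "c"),
                  data.frame(i = "x", j = c("a", "b", "c"), w = c(1, 1, 2)),
                  seeds = list(a = 1L, b = 2L, c = 3L))
  expect_equal(unname(fixed_point_oracle(g2)["x", ]), c(0.25, 0.25, 0.5))

  # no non-seeds -> initialization returned unchanged
  g3 <- toy_graph(c("a", "b"), data.frame(i = "a", j = "b", w = 1),
                  seeds = list(a = 1L, b = 2L))
  expect_equal(fixed_point_oracle(g3), init_labels(g3),
               ignore_attr = "iterations")

  # residual of the update equation at the fixed point
  set.seed(41)
  g4 <- random_cooc_graph(15, 4)
  Q <- fixed_point_oracle(g4)
  attr(Q, "iterations") <- 0L
  expect_lt(max(abs(propagate(g4, Q, 1) - Q)), 1e-10)
})

test_that("propagation converges to the harmonic fixed point", {
  set.seed(51)
  for (rep in 1:10) {
    g <- random_cooc_graph(sample(5:20, 1), sample(1:5, 1))
    Q <- propagate(g, init_labels(g), iterations = 500)
    expect_lt(max(abs(Q - fixed_point_oracle(g))), 1e-6)
  }
  # early stopping by tolerance reaches the same answer
  g <- random_cooc_graph(12, 3)
  Qt <- propagate(g, init_labels(g), iterations = 10000, tol = 1e-12)
  expect_lt(max(abs(Qt - fixed_point_oracle(g))), 1e-8)
  expect_lt(attr(Qt, "iterations"), 10000)
})

test_that("homophily: within-cluster labels are more similar than across", {
  # two 3-vertex clusters, each anchored to its own seed
  edges <- data.frame(
    i = c("a", "x1", "x1", "x2", "b", "y1", "y1", "y2", "x3"),
    j = c("x1", "x2", "x3", "x3", "y1", "y2", "y3", "y3", "y1"),
    w = c(1, 1, 1, 1, 1, 1, 1, 1, 0.05))
  g <- toy_graph(c("a", "b", "x1", "x2", "x3", "y1", "y2", "y3"), edges,
                 seeds = list(a = 1L, b = 2L))
  Q <- propagate(g, init_labels(g), iterations = 100)
  within <- cosine(Q["x1", ], Q["x2", ])
  across <- cosine(Q["x1", ], Q["y2", ])
  expect_gt(within, across)
})

test_that("strengthening a seed edge cannot lower that seed's influence", {
  set.seed(61)
  for (rep in 1:5) {
    g <- random_cooc_graph(10, 3)
    ns <- setdiff(g$vertices, names(g$seed_dims))[1]
    sd <- names(g$seed_dims)[1]
    d <- g$seed_dims[[sd]]
    before <- fixed_point_oracle(g)[ns, d]
    g$W[ns, sd] <- g$W[sd, ns] <- g$W[ns, sd] + 0.5
    after <- fixed_point_oracle(g)[ns, d]
    expect_gte(after, before - 1e-12)
  }
})

test_that("rank_lp ranks by label cosine with the standard tie-break", {
  out <- small_synth(rng_seed = 5, noise = 0, n_seed = 20L, n_swt = 8L,
                     docs = 6L)
  m <- fit_lp(out$source_corpus, out$target_corpus, out$lexicon)
  tm <- names(out$gold_swt)[1]
  r <- rank_lp(m, tm)
  brute <- vapply(rownames(m$target$labels), function(k) {
    cosine(m$source$labels[tm, ], m$target$labels[k, ])
  }, numeric(1))
  freq <- m$target$vocab$freq
  ord <- order(-brute, -ifelse(names(brute) %in% names(freq),
                               freq[names(brute)], 0),
               names(brute), method = "radix")
  expect_equal(r$candidate, names(brute)[ord])
  # excluding seeds removes exactly the target seed vertices
  r2 <- rank_lp(m, tm, include_seeds = FALSE)
  expect_false(any(r2$candidate %in% out$lexicon$target))
  expect_error(rank_lp(m, "no such term"), "not in source graph")
})
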