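# A fixed lp_model is expensive to build per test, so the MWT fixture world
# is created once: 20 seeds, a couple of planted SWT pairs and two planted
# MWT pairs (one 2-to-2, one 2-to-1).
mwt_world <- local({
  out <- small_synth(rng_seed = 13, noise = 0, n_seed = 20L, n_swt = 5L,
                     mwt_counts = c("2-2" = 1L, "2-1" = 1L), docs = 8L,
                     mwt_occ = 4L)
  model <- fit_lp(explode_mwt(out$source_corpus), out$target_corpus,
                  out$lexicon)
  index <- build_word_index(build_vocabulary(out$target_corpus))
  list(out = out, model = model, index = index)
})

test_that("explode_mwt splits every multi-token occurrence into words", {
  corp <- one_doc_corpus(list(c("a", "b", "c")), list(list(c(0, 3))),
                         lang = "zh")
  ex <- explode_mwt(corp)
  t <- ex$documents[[1]]$terms
  expect_equal(nrow(t), 3)
  expect_equal(t$start, 0:2)
  expect_equal(t$end, 1:3)
  v <- build_vocabulary(ex)
  expect_setequal(v$terms, c("a", "b", "c"))
})

test_that("component candidate words carry the best containing-term score", {
  m <- mwt_world$model
  mwts <- names(mwt_world$out$gold_mwt)
  comp <- term_words(mwts[1])[1]
  words <- component_candidate_words(comp, m, K = 100)
  # every word comes from a top-K term and carries the max containing score
  r <- rank_lp(m, comp)
  top <- head(r, 100)
  for (w in names(head(words, 10))) {
    containing <- top$score[vapply(top$candidate, function(k) {
      w %in% term_words(k)
    }, logical(1))]
    expect_equal(unname(words[w]), max(containing))
  }
  expect_length(component_candidate_words(comp, m, K = 0), 0)
})

test_that("multi-word top-K terms donate each of their words", {
  # crafted 3-term model: "failure" occurs only inside "heart failure",
  # so it must carry that term's score; "heart" takes the max over its
  # containing terms
  src <- matrix(c(1, 0), 1, 2, dimnames = list("comp", NULL))
  tgt <- rbind("heart failure" = c(0.9, 0.1),
               "angina" = c(0.5, 0.5),
               "heart" = c(0, 1))
  attr(src, "iterations") <- attr(tgt, "iterations") <- 10L
  fake <- structure(list(
    source = list(labels = src),
    target = list(labels = tgt, graph = list(seed_dims = list()),
                  vocab = list(freq = c("heart failure" = 2L, angina = 1L,
                                        heart = 1L)))),
    class = "lp_model")
  words <- component_candidate_words("comp", fake, K = 3)
  hf <- cosine(c(1, 0), c(0.9, 0.1))
  expect_equal(unname(words["failure"]), hf)
  expect_equal(unname(words["heart"]), max(hf, cosine(c(1, 0), c(0, 1))))
  expect_equal(unname(words["angina"]), cosine(c(1, 0), c(0.5, 0.5)))
})

test_that("intersect_candidates keeps shared words with per-component sims", {
  a <- c(atrial = 0.9, fibrillation = 0.8, syncope = 0.3)
  b <- c(fibrillation = 0.7, atrial = 0.6, stools = 0.2)
  inter <- intersect_candidates(list(c1 = a, c2 = b))
  expect_setequal(inter$words, c("atrial", "fibrillation"))
  expect_equal(inter$sims["atrial", "c1"], 0.9)
  expect_equal(inter$sims["atrial", "c2"], 0.6)
  # disjoint -> empty; three identical sets keep all q words
  expect_length(intersect_candidates(list(c(x = 1), c(y = 1)))$words, 0)
  s <- c(p = 0.5, q = 0.4, r = 0.3)
  expect_length(intersect_candidates(list(s, s, s))$words, 3)
  expect_error(intersect_candidates(list(a)), ">= 2")
})

test_that("enumerate_combinations equals brute-force powerset filtering", {
  corp <- one_doc_corpus(
    list(c("atrial", "fibrillation", "dysphagia", "acidosis", "heart")),
    list(list(c(0, 2), c(2, 3), c(3, 4), c(4, 5))))
  idx <- build_word_index(build_vocabulary(corp))
  inter <- c("atrial", "fibrillation", "dysphagia", "stools")
  combos <- enumerate_combinations(inter, 2, idx)
  got <- lapply(combos, function(cb) sort(cb$words))
  # brute force over the full powerset of sizes <= 2
  brute <- list()
  for (j in 1:2) {
    for (s in combn(inter, j, simplify = FALSE)) {
      hits <- lookup_word_set(idx, s)
      if (length(hits)) brute[[length(brute) + 1L]] <- sort(s)
    }
  }
  expect_setequal(vapply(got, paste, character(1), collapse = "|"),
                  vapply(brute, paste, character(1), collapse = "|"))
  expect_equal(attr(combos, "examined"), choose(4, 1) + choose(4, 2))
})

test_that("examined-subset count is sum of binomials; q=12 n=3 gives 298", {
  empty_idx <- structure(list(), class = "term_word_index")
  for (q in c(3, 7, 12)) for (n_max in 1:4) {
    combos <- enumerate_combinations(paste0("w", seq_len(q)), n_max,
                                     empty_idx)
    expect_length(combos, 0)
    expect_equal(attr(combos, "examined"),
                 sum(choose(q, seq_len(n_max))))
  }
  c12 <- enumerate_combinations(paste0("w", 1:12), 3, empty_idx)
  expect_equal(attr(c12, "examined"), 298)
})

test_that("score_combination averages pair similarities", {
  S <- matrix(c(0.4, 0.6), nrow = 1, dimnames = list("w", c("c1", "c2")))
  expect_equal(score_combination("w", S), 0.5)
  # all sims equal s -> score s
  S2 <- matrix(0.3, 2, 3, dimnames = list(c("u", "v"), c("a", "b", "c")))
  expect_equal(score_combination(c("u", "v"), S2), 0.3)
  # a word missing from the matrix contributes 0 to every pair
  expect_equal(score_combination(c("w", "missing"), S), 0.25)
  # best-match mode takes each component's max
  S3 <- matrix(c(0.8, 0.2, 0.1, 0.6), 2,
               dimnames = list(c("u", "v"), c("a", "b")))
  expect_equal(score_combination(c("u", "v"), S3, mode = "best-match"),
               mean(c(0.8, 0.6)))
  # permutation invariance in components and words
  expect_equal(score_combination(c("v", "u"), S3[2:1, 2:1]),
               score_combination(c("u", "v"), S3))
  expect_error(score_combination(character(0), S), "empty")
})

test_that("align_mwt recovers the planted translation end to end", {
  out <- mwt_world$out
  for (mwt in names(out$gold_mwt)) {
    planted <- out$gold_mwt[[mwt]]
    r <- align_mwt(mwt, mwt_world$model, mwt_world$index, K = 100)
    expect_true(planted %in% r$candidate)
    expect_lte(match(planted, r$candidate), 5)
    # every ranked term really occurs in the target corpus
    expect_true(all(r$candidate %in%
                      names(mwt_world$model$target$vocab$freq)))
  }
  expect_error(align_mwt("zt001", mwt_world$model, mwt_world$index),
               "need >= 2")
  expect_error(align_mwt("novel words", mwt_world$model, mwt_world$index),
               "fewer than 2 resolvable")
})
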