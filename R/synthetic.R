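#' Configuration for the synthetic comparable-corpus generator
#'
#' The generator emulates the data regime of bilingual clinical discharge
#' summaries: two monolingual corpora that are *comparable* but not
#' parallel, a scarce seed lexicon of single-word term pairs, planted
#' single-word translation pairs whose cross-language affinity to seed
#' pairs is shared (the signal every method tries to recover),
#' language-asymmetric sentence lengths (the source side packs more terms
#' per sentence), per-language context noise, and rare m-to-n multi-word
#' translation pairs whose default length distribution follows the observed
#' 37-pair distribution (11 2-to-1, 14 2-to-2, 2 3-to-2, 1 3-to-3, 7
#' 1-to-2, 2 2-to-3).
#'
#' @param n_seed_pairs number of seed pairs (default 50; desk-scale stand-in
#'   for the scarce real seed set).
#' @param n_swt_pairs planted single-word translation pairs (default 30).
#' @param mwt_pair_counts named integer vector, names `"m-n"`; default the
#'   observed length distribution above.
#' @param docs_per_language nominal documents per corpus (default 40).
#' @param sentences_per_doc named `c(source=, target=)` (default 10 / 20).
#' @param terms_per_sentence named `c(source=, target=)` (default 6 / 3):
#'   the source side mimics long run-on sentences by packing more annotated
#'   terms per sentence.
#' @param affinity_sparsity preferred seed dimensions per planted pair
#'   (default 3); must not exceed the per-topic seed-dimension count.
#' @param n_topics number of topic blocks (default `n_seed_pairs %/% 10`,
#'   at least 1). Seed dimensions and planted pairs are partitioned into
#'   topics and every sentence draws all of its terms from one topic,
#'   mimicking the topical organization of clinical narratives; without it
#'   the co-occurrence graph degenerates into an uninformative hairball.
#' @param noise_rate named `c(source=, target=)` probability of replacing a
#'   flanking seed with a uniformly random one (default 0.05 each).
#' @param flank_rate probability that each side of a term slot carries a
#'   seed term at all (default 1). Lowering it makes dictionary context
#'   scarcer for every method at once; sides without a seed expose the
#'   occurrence to whatever the neighbouring slots provide.
#' @param mwt_term_occurrences occurrences of each full multi-word term and
#'   of its target translation (default 3; deliberately low — multi-word
#'   terms are rare even when their component words are frequent).
#' @param rng_seed integer RNG seed.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_seed_pairs = 50L,
                         n_swt_pairs = 30L,
                         mwt_pair_counts = c("2-1" = 11L, "2-2" = 14L,
                                             "3-2" = 2L, "3-3" = 1L,
                                             "1-2" = 7L, "2-3" = 2L),
                         docs_per_language = 40L,
                         sentences_per_doc = c(source = 10L, target = 20L),
                         terms_per_sentence = c(source = 6L, target = 3L),
                         affinity_sparsity = 3L,
                         n_topics = NULL,
                         noise_rate = c(source = 0.05, target = 0.05),
                         flank_rate = 1,
                         mwt_term_occurrences = 3L,
                         rng_seed = 1L) {
  if (is.null(n_topics)) n_topics <- max(1L, as.integer(n_seed_pairs) %/% 10L)
  cfg <- list(n_seed_pairs = as.integer(n_seed_pairs),
              n_swt_pairs = as.integer(n_swt_pairs),
              mwt_pair_counts = mwt_pair_counts,
              docs_per_language = as.integer(docs_per_language),
              sentences_per_doc = sentences_per_doc,
              terms_per_sentence = terms_per_sentence,
              affinity_sparsity = as.integer(affinity_sparsity),
              n_topics = as.integer(n_topics),
              noise_rate = noise_rate,
              flank_rate = as.numeric(flank_rate),
              mwt_term_occurrences = as.integer(mwt_term_occurrences),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_seed_pairs >= 1, cfg$n_swt_pairs >= 0,
            all(cfg$mwt_pair_counts >= 0),
            all(c("source", "target") %in% names(cfg$sentences_per_doc)),
            all(c("source", "target") %in% names(cfg$terms_per_sentence)),
            all(cfg$noise_rate >= 0), all(cfg$noise_rate <= 1),
            cfg$flank_rate >= 0, cfg$flank_rate <= 1,
            cfg$mwt_term_occurrences >= 1, cfg$n_topics >= 1)
  if (cfg$affinity_sparsity > cfg$n_seed_pairs %/% cfg$n_topics) {
    stop("infeasible config: affinity_sparsity (", cfg$affinity_sparsity,
         ") exceeds the seed dimensions per topic (",
         cfg$n_seed_pairs %/% cfg$n_topics, ")")
  }
  if (length(cfg$mwt_pair_counts)) {
    shapes <- strsplit(names(cfg$mwt_pair_counts), "-", fixed = TRUE)
    if (any(vapply(shapes, length, integer(1)) != 2L)) {
      stop("mwt_pair_counts names must look like \"m-n\"")
    }
  }
  structure(cfg, class = "synth_config")
}

#' Generate paired comparable corpora with a planted bilingual lexicon
#'
#' Each planted pair draws one sparse affinity set of `affinity_sparsity`
#' distinct seed dimensions, shared across languages (supports are unique
#' across pairs so planted signals stay separable). A corpus is a stream of
#' slots; each slot realizes one planted term flanked by one seed term on
#' each side, both drawn uniformly from the pair's affinity set and each
#' replaced by a uniformly random seed with the language's noise
#' probability. Multi-word pairs contribute their component words to the
#' slot pool as frequent single-word terms (sharing the pair's affinity)
#' while the full m-word source term and its n-word target translation are
#' planted only `mwt_term_occurrences` times each — multi-word terms are
#' rare, their components are not. Identical configs and seeds produce
#' byte-identical output.
#'
#' @param config a [synth_config()].
#' @return a `synth_output` list: `source_corpus`, `target_corpus`
#'   (`bilex_corpus`), `lexicon` (`seed_lexicon`), `gold_swt`, `gold_mwt`
#'   (named lists source key -> target keys), and `pairs` (a data frame of
#'   planted pairs with their affinity sets, for diagnostics).
#' @export
generate_comparable_corpora <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$rng_seed)
  n_seed <- config$n_seed_pairs
  seed_src <- sprintf("zs%03d", seq_len(n_seed))
  seed_tgt <- sprintf("es%03d", seq_len(n_seed))

  # --- planted pairs and their shared sparse affinities ------------------
  swt_src <- sprintf("zt%03d", seq_len(config$n_swt_pairs))
  swt_tgt <- sprintf("et%03d", seq_len(config$n_swt_pairs))

  mwt <- expand_mwt_shapes(config$mwt_pair_counts)
  mwt_src <- character(0); mwt_tgt <- character(0)
  if (nrow(mwt)) {
    mwt_src <- vapply(seq_len(nrow(mwt)), function(p) {
      paste(sprintf("zm%03dw%d", p, seq_len(mwt$m[p])), collapse = " ")
    }, character(1))
    mwt_tgt <- vapply(seq_len(nrow(mwt)), function(p) {
      paste(sprintf("em%03dw%d", p, seq_len(mwt$n[p])), collapse = " ")
    }, character(1))
  }

  n_pairs <- config$n_swt_pairs + nrow(mwt)
  # topics interleave over seed dimensions (so any contiguous subset of the
  # lexicon, e.g. a partial reveal, still covers every topic); pairs are
  # assigned round-robin
  dim_topic <- rep_len(seq_len(config$n_topics), n_seed)
  topic_dims <- split(seq_len(n_seed), dim_topic)
  pair_topic <- rep_len(seq_len(config$n_topics), max(n_pairs, 1L))
  aff <- draw_unique_affinities(
    lapply(seq_len(n_pairs), function(p) topic_dims[[pair_topic[p]]]),
    config$affinity_sparsity)
  swt_aff <- aff[seq_len(config$n_swt_pairs)]
  mwt_aff <- aff[config$n_swt_pairs + seq_len(nrow(mwt))]
  swt_topic <- pair_topic[seq_len(config$n_swt_pairs)]
  mwt_topic <- pair_topic[config$n_swt_pairs + seq_len(nrow(mwt))]

  # slot pool: swt terms + mwt component words, each with affinity + topic
  pool_src <- c(stats::setNames(swt_aff, swt_src),
                mwt_component_pool(mwt_src, mwt_aff))
  pool_src_topic <- c(stats::setNames(swt_topic, swt_src),
                      mwt_component_topics(mwt_src, mwt_topic))
  pool_tgt <- stats::setNames(swt_aff, swt_tgt)
  pool_tgt_topic <- stats::setNames(swt_topic, swt_tgt)
  # seeds-only fallback: plant the seeds themselves, topic-wide affinity
  if (!length(pool_src)) {
    pool_src <- stats::setNames(topic_dims[dim_topic], seed_src)
    pool_src_topic <- stats::setNames(dim_topic, seed_src)
    pool_tgt <- stats::setNames(topic_dims[dim_topic], seed_tgt)
    pool_tgt_topic <- stats::setNames(dim_topic, seed_tgt)
  } else if (!length(pool_tgt)) {
    pool_tgt <- stats::setNames(topic_dims[dim_topic], seed_tgt)
    pool_tgt_topic <- stats::setNames(dim_topic, seed_tgt)
  }

  rare_src <- stats::setNames(mwt_aff, mwt_src)
  rare_tgt <- stats::setNames(mwt_aff, mwt_tgt)
  rare_src_topic <- stats::setNames(mwt_topic, mwt_src)
  rare_tgt_topic <- stats::setNames(mwt_topic, mwt_tgt)

  src <- generate_side("zh", seed_src, pool_src, pool_src_topic,
                       rare_src, rare_src_topic, config, "source")
  tgt <- generate_side("en", seed_tgt, pool_tgt, pool_tgt_topic,
                       rare_tgt, rare_tgt_topic, config, "target")

  lex <- seed_lexicon(seed_src, seed_tgt)
  gold_swt <- stats::setNames(as.list(swt_tgt), swt_src)
  gold_mwt <- stats::setNames(as.list(mwt_tgt), mwt_src)
  pairs <- data.frame(
    source = c(swt_src, mwt_src), target = c(swt_tgt, mwt_tgt),
    kind = rep(c("swt", "mwt"), c(length(swt_src), length(mwt_src))),
    stringsAsFactors = FALSE)
  pairs$affinity <- aff

  structure(list(source_corpus = src, target_corpus = tgt, lexicon = lex,
                 gold_swt = gold_swt, gold_mwt = gold_mwt, pairs = pairs),
            class = "synth_output")
}

expand_mwt_shapes <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(data.frame(m = integer(), n = integer()))
  }
  shapes <- strsplit(names(counts), "-", fixed = TRUE)
  m <- rep(vapply(shapes, function(s) as.integer(s[1]), integer(1)), counts)
  n <- rep(vapply(shapes, function(s) as.integer(s[2]), integer(1)), counts)
  data.frame(m = m, n = n)
}

# distinct sparse supports (one draw per pair from its topic's dims) so
# planted pairs stay distinguishable
draw_unique_affinities <- function(allowed_dims, k) {
  out <- vector("list", length(allowed_dims))
  seen <- character(0)
  for (p in seq_along(allowed_dims)) {
    dims <- allowed_dims[[p]]
    for (try in 1:1000) {
      a <- sort(dims[sample.int(length(dims), k)])
      key <- paste(a, collapse = ",")
      if (!key %in% seen) break
    }
    seen <- c(seen, key)
    out[[p]] <- a
  }
  out
}

mwt_component_pool <- function(mwt_keys, mwt_aff) {
  if (!length(mwt_keys)) return(list())
  comp <- list()
  for (p in seq_along(mwt_keys)) {
    for (w in term_words(mwt_keys[p])) comp[[w]] <- mwt_aff[[p]]
  }
  comp
}

mwt_component_topics <- function(mwt_keys, mwt_topic) {
  if (!length(mwt_keys)) return(integer(0))
  out <- integer(0)
  for (p in seq_along(mwt_keys)) {
    for (w in term_words(mwt_keys[p])) out[[w]] <- mwt_topic[p]
  }
  out
}

generate_side <- function(lang, seed_words, pool, pool_topic,
                          rare, rare_topic, config, side) {
  tps <- as.integer(config$terms_per_sentence[[side]])
  spd <- as.integer(config$sentences_per_doc[[side]])
  eps <- as.numeric(config$noise_rate[[side]])
  n_seed <- config$n_seed_pairs

  slots_total <- config$docs_per_language * spd * tps
  reps <- max(1L, slots_total %/% length(pool))
  slot_aff <- c(pool, rare)

  # per-topic slot streams -> topically coherent sentences
  sentences_pool <- list()
  for (tp in sort(unique(c(pool_topic, rare_topic)))) {
    terms_t <- c(rep(names(pool)[pool_topic == tp], each = reps),
                 rep(names(rare)[rare_topic == tp],
                     each = config$mwt_term_occurrences))
    terms_t <- sample(terms_t)
    idx <- split(seq_along(terms_t),
                 ceiling(seq_along(terms_t) / tps))
    for (g in idx) {
      sentences_pool[[length(sentences_pool) + 1L]] <- terms_t[g]
    }
  }
  sentences_pool <- sentences_pool[sample.int(length(sentences_pool))]

  n_sent <- length(sentences_pool)
  n_docs <- ceiling(n_sent / spd)
  docs <- vector("list", n_docs)
  k <- 0L
  for (d in seq_len(n_docs)) {
    n_here <- min(spd, n_sent - (d - 1L) * spd)
    sentences <- vector("list", n_here)
    terms <- list()
    for (s in seq_len(n_here)) {
      k <- k + 1L
      tokens <- character(0)
      for (tkey in sentences_pool[[k]]) {
        a <- slot_aff[[tkey]]
        has_l <- stats::runif(1) < config$flank_rate
        has_r <- stats::runif(1) < config$flank_rate
        dl <- if (has_l) noisy_dim(a, n_seed, eps) else NA_integer_
        dr <- if (has_r) noisy_dim(a, n_seed, eps) else NA_integer_
        words <- term_words(tkey)
        base <- length(tokens)
        piece_tokens <- c(if (has_l) seed_words[dl], words,
                          if (has_r) seed_words[dr])
        tokens <- c(tokens, piece_tokens)
        t_start <- base + as.integer(has_l)
        spans <- data.frame(
          start = c(if (has_l) base, t_start,
                    if (has_r) t_start + length(words)),
          end = c(if (has_l) base + 1L, t_start + length(words),
                  if (has_r) t_start + length(words) + 1L))
        spans$sent <- s - 1L
        spans$cat <- "problem"
        terms[[length(terms) + 1L]] <-
          spans[, c("sent", "start", "end", "cat")]
      }
      sentences[[s]] <- tokens
    }
    docs[[d]] <- list(
      doc_id = sprintf("%s%04d", lang, d),
      sentences = sentences,
      terms = do.call(rbind, c(terms, list(make.row.names = FALSE))))
  }
  new_corpus(lang, docs)
}

noisy_dim <- function(affinity, n_seed, eps) {
  d <- affinity[sample.int(length(affinity), 1L)]
  if (eps > 0 && stats::runif(1) < eps) d <- sample.int(n_seed, 1L)
  d
}

#' Reveal only a fraction of the planted seed lexicon
#'
#' Keeps the first `ceiling(fraction * n)` seed pairs; the hidden seeds
#' remain ordinary annotated terms in the corpora and become unlabeled
#' intermediate vertices for label propagation — the seed-scarcity regime.
#'
#' @param lexicon a `seed_lexicon`.
#' @param fraction fraction in (0, 1] of pairs to keep.
#' @return the truncated `seed_lexicon`.
#' @export
reveal_seeds <- function(lexicon, fraction) {
  stopifnot(inherits(lexicon, "seed_lexicon"), fraction > 0, fraction <= 1)
  n <- max(1L, as.integer(ceiling(fraction * nrow(lexicon))))
  seed_lexicon(lexicon$source[seq_len(n)], lexicon$target[seq_len(n)])
}

#' Write a synthetic-output bundle to a directory
#'
#' Emits `source.jsonl`, `target.jsonl` (the corpus dialect read by
#' [read_corpus()]), `seeds.tsv`, `gold_swt.tsv` and `gold_mwt.tsv`.
#'
#' @param output a `synth_output`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_output <- function(output, dir) {
  stopifnot(inherits(output, "synth_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(output$source_corpus, file.path(dir, "source.jsonl"))
  write_corpus(output$target_corpus, file.path(dir, "target.jsonl"))
  write_lexicon(output$lexicon, file.path(dir, "seeds.tsv"))
  write_lexicon(output$gold_swt, file.path(dir, "gold_swt.tsv"))
  write_lexicon(output$gold_mwt, file.path(dir, "gold_mwt.tsv"))
  invisible(dir)
}

#' @export
print.synth_output <- function(x, ...) {
  cat("<synth_output>\n  "); print(x$source_corpus)
  cat("  "); print(x$target_corpus)
  cat("  ", nrow(x$lexicon), "seed pairs,", length(x$gold_swt),
      "gold SWT pairs,", length(x$gold_mwt), "gold MWT pairs\n")
  invisible(x)
}
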