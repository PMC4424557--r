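#' Write a lexicon (seed or gold) as TSV
#'
#' @param pairs a `seed_lexicon` data frame, or a named list (source key ->
#'   character vector of target keys) as returned by [read_gold_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(pairs, path) {
  if (is.data.frame(pairs)) {
    lines <- paste(pairs$source, pairs$target, sep = "\t")
  } else {
    lines <- unlist(lapply(names(pairs), function(s) {
      paste(s, pairs[[s]], sep = "\t")
    }))
  }
  writeLines(c("source_term\ttarget_term", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Export context vectors as TSV (term, dimension, weight)
#' @param vectors sparse matrix from [extract_context_vectors()].
#' @param path output path.
#' @export
write_vectors_tsv <- function(vectors, path) {
  M <- methods::as(methods::as(vectors, "generalMatrix"), "TsparseMatrix")
  ord <- order(M@i, M@j)
  lines <- sprintf("%s\t%d\t%g", rownames(vectors)[M@i[ord] + 1L],
                   M@j[ord], M@x[ord])
  writeLines(c("term\tdimension\tweight", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Export a graph as a TSV edge list (term_i, term_j, weight)
#' @param graph a `cooc_graph`.
#' @param path output path.
#' @export
write_graph_tsv <- function(graph, path) {
  W <- methods::as(methods::as(graph$W, "generalMatrix"), "TsparseMatrix")
  keep <- W@i < W@j
  ord <- order(W@i[keep], W@j[keep])
  i <- (W@i[keep])[ord]; j <- (W@j[keep])[ord]; x <- (W@x[keep])[ord]
  lines <- sprintf("%s\t%s\t%g", graph$vertices[i + 1L],
                   graph$vertices[j + 1L], x)
  writeLines(c("term_i\tterm_j\tweight", lines), path, useBytes = TRUE)
  invisible(path)
}

#' Export rankings as TSV (test_term, rank, candidate, score)
#' @param rankings named list of `candidate_ranking` data frames.
#' @param path output path.
#' @param top_n truncate each ranking (default 100).
#' @export
write_rankings_tsv <- function(rankings, path, top_n = 100L) {
  lines <- unlist(lapply(names(rankings), function(tm) {
    r <- utils::head(rankings[[tm]], top_n)
    sprintf("%s\t%d\t%s\t%g", tm, r$rank, r$candidate, r$score)
  }))
  writeLines(c("test_term\trank\tcandidate\tscore", lines), path,
             useBytes = TRUE)
  invisible(path)
}

#' Run the full induction pipeline
#'
#' Wires the stages end to end: read corpora + lexicons, extract context
#' vectors, build graphs, propagate labels, rank every non-seed source
#' single-word term by both the context-similarity baseline and label
#' propagation, align every gold multi-word term, and evaluate Top-N
#' accuracy where gold lexicons are given. All intermediate artifacts are
#' written as TSV under `out_dir` so stages can be inspected and re-run
#' independently; reruns on identical inputs are byte-identical.
#'
#' @param source_corpus,target_corpus paths to corpus JSONL files or
#'   `bilex_corpus` objects.
#' @param seed_lexicon path to the seed TSV or a `seed_lexicon`.
#' @param gold_swt,gold_mwt optional gold lexicon paths or named lists.
#' @param out_dir output directory (created if missing).
#' @param iterations,K,edge_weight,score_mode,policy standard knobs
#'   (defaults 10 / 100 / cosine / pairs-mean).
#' @param topn accuracy cutoffs.
#' @return invisible list with models, rankings and reports.
#' @export
run_pipeline <- function(source_corpus, target_corpus, seed_lexicon,
                         gold_swt = NULL, gold_mwt = NULL,
                         out_dir = "bilex-out",
                         iterations = 10L, K = 100L,
                         edge_weight = "cosine", score_mode = "pairs-mean",
                         policy = window_policy(),
                         topn = c(1L, 10L, 20L, 50L, 100L)) {
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage \"", name, "\" failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[bilex] %-18s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }
  if (is.character(source_corpus)) {
    source_corpus <- stage("read_corpus(src)", read_corpus(source_corpus, "zh"))
  }
  if (is.character(target_corpus)) {
    target_corpus <- stage("read_corpus(tgt)", read_corpus(target_corpus, "en"))
  }
  if (is.character(seed_lexicon)) {
    seed_lexicon <- stage("read_seed_lexicon", read_seed_lexicon(seed_lexicon))
  }
  if (is.character(gold_swt)) gold_swt <- read_gold_lexicon(gold_swt)
  if (is.character(gold_mwt)) gold_mwt <- read_gold_lexicon(gold_mwt)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  model <- stage("fit_lp", fit_lp(source_corpus, target_corpus, seed_lexicon,
                                  policy = policy, iterations = iterations,
                                  edge_weight = edge_weight))
  write_vectors_tsv(model$source$vectors, file.path(out_dir, "vectors_source.tsv"))
  write_vectors_tsv(model$target$vectors, file.path(out_dir, "vectors_target.tsv"))
  write_graph_tsv(model$source$graph, file.path(out_dir, "graph_source.tsv"))
  write_graph_tsv(model$target$graph, file.path(out_dir, "graph_target.tsv"))

  seed_src <- unique(seed_lexicon$source)
  swts <- model$source$vocab$terms[
    model$source$vocab$nwords == 1L &
      !(model$source$vocab$terms %in% seed_src)]
  test_swt <- if (!is.null(gold_swt)) {
    intersect(names(gold_swt), model$source$vocab$terms)
  } else swts

  # candidate policy: known (seed) translations are excluded -- test terms
  # are never covered by the seed dictionary
  rank_all <- stage("rank", {
    keep <- !(rownames(model$target$vectors) %in% seed_lexicon$target)
    base <- lapply(test_swt, function(tm) {
      rank_baseline(model$source$vectors[tm, ],
                    model$target$vectors[keep, , drop = FALSE],
                    model$target$vocab$freq)
    })
    lp <- lapply(test_swt, function(tm) rank_lp(model, tm,
                                                include_seeds = FALSE))
    list(baseline = stats::setNames(base, test_swt),
         lp = stats::setNames(lp, test_swt))
  })
  write_rankings_tsv(rank_all$baseline, file.path(out_dir, "rank_baseline.tsv"))
  write_rankings_tsv(rank_all$lp, file.path(out_dir, "rank_lp.tsv"))

  mwt_rankings <- NULL
  if (!is.null(gold_mwt) && length(gold_mwt)) {
    mwt_model <- stage("fit_lp(exploded)", fit_lp(
      explode_mwt(source_corpus), target_corpus, seed_lexicon,
      policy = policy, iterations = iterations, edge_weight = edge_weight))
    index <- build_word_index(model$target$vocab)
    mwts <- names(gold_mwt)[vapply(names(gold_mwt), term_length,
                                   integer(1)) >= 2L]
    mwt_rankings <- stage("align_mwt", stats::setNames(lapply(mwts, function(q) {
      tryCatch(align_mwt(q, mwt_model, index, K = K, score_mode = score_mode),
               error = function(e) make_ranking(stats::setNames(numeric(0),
                                                                character(0))))
    }), mwts))
    write_rankings_tsv(mwt_rankings, file.path(out_dir, "rank_mwt.tsv"))
    examined <- vapply(mwt_rankings, function(r) {
      e <- attr(r, "examined"); if (is.null(e)) 0L else as.integer(e)
    }, integer(1))
    message("[bilex] subset diagnostics: ", sum(examined),
            " subsets examined, ",
            sum(vapply(mwt_rankings, nrow, integer(1))), " survivors")
  }

  reports <- list()
  if (!is.null(gold_swt)) {
    reports$baseline <- top_n_accuracy(rank_all$baseline, gold_swt, topn,
                                       model$target$vocab)
    reports$lp <- top_n_accuracy(rank_all$lp, gold_swt, topn,
                                 model$target$vocab)
    write_accuracy_tsv(reports, file.path(out_dir, "accuracy_swt.tsv"))
  }
  if (!is.null(mwt_rankings) && !is.null(gold_mwt)) {
    reports$mwt <- top_n_accuracy(mwt_rankings, gold_mwt, topn,
                                  model$target$vocab)
    write_accuracy_tsv(reports["mwt"], file.path(out_dir, "accuracy_mwt.tsv"))
  }
  invisible(list(model = model, rankings = rank_all,
                 mwt_rankings = mwt_rankings, reports = reports))
}

write_accuracy_tsv <- function(reports, path) {
  lines <- unlist(lapply(names(reports), function(nm) {
    a <- reports[[nm]]$accuracy
    sprintf("%s\t%d\t%.6f\t%.6f", nm, a$N, a$acc, a$acc_excluded)
  }))
  writeLines(c("method\tN\tacc\tacc_excluded", lines), path, useBytes = TRUE)
  invisible(path)
}
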