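#' Top-N accuracy against a gold lexicon
#'
#' For each test term, the hit rank is the rank of its highest-ranked gold
#' translation (exact term-key match; permissible near-translations do not
#' count). `Acc_N` is the fraction of test terms with hit rank <= N. Terms
#' with an empty ranking are misses. Ranked terms without a gold entry are
#' excluded and counted as unevaluable. When the target vocabulary is
#' supplied, terms none of whose gold translations occur in the target
#' corpus are additionally reported, and a second accuracy with those terms
#' excluded from the denominator is emitted alongside the strict one.
#'
#' @param rankings named list: source term key -> `candidate_ranking` (or
#'   any data frame with a `candidate` column in rank order).
#' @param gold named list: source term key -> character vector of
#'   acceptable target term keys (see [read_gold_lexicon()]).
#' @param Ns integer vector of N values (default `c(1, 10, 20, 50, 100)`).
#' @param target_vocab optional `bilex_vocab` of the target corpus, used
#'   only for the gold-absent diagnostic.
#' @return an `accuracy_report`: list with `accuracy` (data frame `N`,
#'   `acc`, `acc_excluded`), `hits` (per-term hit rank, `NA` = miss),
#'   `n_evaluated`, `n_unevaluable`, `gold_absent` (term keys).
#' @export
top_n_accuracy <- function(rankings, gold, Ns = c(1L, 10L, 20L, 50L, 100L),
                           target_vocab = NULL) {
  stopifnot(is.list(rankings), is.list(gold))
  Ns <- sort(unique(as.integer(Ns)))
  terms <- names(rankings)
  unevaluable <- terms[!(terms %in% names(gold))]
  terms <- setdiff(terms, unevaluable)

  hits <- vapply(terms, function(tm) {
    r <- rankings[[tm]]
    if (is.null(r) || nrow(r) == 0L) return(NA_integer_)
    pos <- which(r$candidate %in% gold[[tm]])
    if (length(pos)) min(pos) else NA_integer_
  }, integer(1))

  gold_absent <- character(0)
  if (!is.null(target_vocab)) {
    gold_absent <- terms[vapply(terms, function(tm) {
      !any(gold[[tm]] %in% target_vocab$terms)
    }, logical(1))]
  }
  kept <- setdiff(terms, gold_absent)

  acc <- vapply(Ns, function(N) {
    if (!length(terms)) return(NA_real_)
    sum(!is.na(hits) & hits <= N) / length(terms)
  }, numeric(1))
  acc_ex <- vapply(Ns, function(N) {
    if (!length(kept)) return(NA_real_)
    sum(!is.na(hits[kept]) & hits[kept] <= N) / length(kept)
  }, numeric(1))

  structure(list(
    accuracy = data.frame(N = Ns, acc = acc, acc_excluded = acc_ex),
    hits = hits,
    n_evaluated = length(terms),
    n_unevaluable = length(unevaluable),
    gold_absent = gold_absent),
    class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>", x$n_evaluated, "terms evaluated,",
      x$n_unevaluable, "unevaluable,",
      length(x$gold_absent), "with gold absent from target corpus\n")
  a <- x$accuracy
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  Acc_%-4d %6.2f%%", a$N[i], 100 * a$acc[i]))
    if (!is.na(a$acc_excluded[i]) && length(x$gold_absent)) {
      cat(sprintf("  (%.2f%% excluding gold-absent)", 100 * a$acc_excluded[i]))
    }
    cat("\n")
  }
  invisible(x)
}
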