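#' Term identity helpers
#'
#' A term is identified by its language plus the ordered tuple of its
#' case-folded words. Inside `bilex` a term is carried around as a single
#' canonical key: the words joined by single spaces. English words are
#' lower-cased; scripts without case (e.g. Chinese) pass through `tolower()`
#' unchanged, so one folding rule covers both sides.
#'
#' @param words character vector of surface words (one element per word).
#' @return `term_key()` returns a length-1 character key; `term_words()`
#'   splits a key back into its word tuple.
#' @examples
#' term_key(c("Atrial", "Fibrillation"))  # "atrial fibrillation"
#' term_words("atrial fibrillation")
#' @export
term_key <- function(words) {
  stopifnot(is.character(words), length(words) >= 1L, !anyNA(words))
  if (any(!nzchar(words))) stop("term words must be non-empty strings")
  paste(tolower(words), collapse = " ")
}

#' @rdname term_key
#' @param key a canonical term key produced by [term_key()].
#' @export
term_words <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  strsplit(key, " ", fixed = TRUE)[[1L]]
}

#' Number of words in a term key
#' @inheritParams term_words
#' @return integer word count; keys with more than one word are multi-word
#'   terms (MWTs), the rest single-word terms (SWTs).
#' @export
term_length <- function(key) length(term_words(key))

# canonical key for order-insensitive word-SET lookup (duplicates collapsed)
word_set_key <- function(words) paste(sort(unique(tolower(words))), collapse = " ")
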