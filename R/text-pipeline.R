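#' Text preparation configuration
#'
#' Two modes are supported. In `"winnowed"` mode (the default, and the one
#' that performs best) each description is reduced to its keyword-bearing
#' sentences before tokenization, the joined text is truncated at 25,000
#' characters and the vocabulary is capped at 3,000 words. In `"full_text"`
#' mode the whole description is kept, truncated at 200,000 characters, with
#' a 5,000-word vocabulary.
#'
#' @param mode `"winnowed"` or `"full_text"`.
#' @param truncate_chars Character budget after winnowing/assembly.
#' @param num_words Vocabulary bound: only the `num_words - 1` most frequent
#'   words receive usable indices.
#' @param fit_on Fit the vocabulary on `"train"` texts only (default, no
#'   leakage from evaluation texts) or on `"all"` texts.
#' @param strict_sentence If `TRUE`, a kept sentence must itself satisfy the
#'   trait's full rule; by default a sentence matching any single trait
#'   keyword is kept (subject to the required-keyword gate).
#' @return A list of class `text_prep_config`.
#' @export
text_prep_config <- function(mode = c("winnowed", "full_text"),
                             truncate_chars = NULL, num_words = NULL,
                             fit_on = c("train", "all"),
                             strict_sentence = FALSE) {
  mode <- match.arg(mode)
  truncate_chars <- truncate_chars %||%
    switch(mode, winnowed = 25000L, full_text = 200000L)
  num_words <- num_words %||% switch(mode, winnowed = 3000L, full_text = 5000L)
  stopifnot(truncate_chars > 0, num_words >= 2)
  structure(list(mode = mode, truncate_chars = as.integer(truncate_chars),
                 num_words = as.integer(num_words),
                 fit_on = match.arg(fit_on),
                 strict_sentence = isTRUE(strict_sentence)),
            class = "text_prep_config")
}

#' Split text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace; a trailing
#' fragment without terminal punctuation is kept as a sentence. This simple
#' rule occasionally splits at abbreviations, which only moves filler text
#' between sentences and is absorbed downstream.
#'
#' @param text A single string.
#' @return Character vector of sentences (punctuation retained).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}

#' Winnow a description down to its keyword-bearing sentences
#'
#' Keeps sentences matching any of the trait's keywords and discards the
#' rest. If any *required* keyword has no matching sentence at all the
#' result is empty — for fermentation and acetate production, at least one
#' sentence must match "ferment" for any sentence to be kept. Duplicated
#' kept sentences are dropped (first occurrence survives), the survivors are
#' joined with single spaces, and the result is truncated at
#' `config$truncate_chars` characters.
#'
#' Winnowing is idempotent: winnowing an already-winnowed text returns it
#' unchanged.
#'
#' @param text A species description.
#' @param trait A [trait_definition()].
#' @param config A [text_prep_config()] with `mode = "winnowed"`.
#' @return The winnowed text (possibly an empty string).
#' @export
winnow <- function(text, trait, config = text_prep_config()) {
  stopifnot(inherits(trait, "trait_definition"),
            inherits(config, "text_prep_config"))
  if (config$mode != "winnowed")
    stop("winnow() requires mode = 'winnowed'", call. = FALSE)
  sents <- split_sentences(text)
  if (length(sents) == 0L) return("")

  if (config$strict_sentence) {
    keep <- matches_trait(sents, trait)
  } else {
    kw <- c(trait$required, trait$any_of)
    hits <- vapply(kw, function(k) keyword_match(sents, k),
                   logical(length(sents)))
    hits <- matrix(hits, nrow = length(sents))
    keep <- rowSums(hits) > 0
  }
  # gate: every required keyword needs at least one matching sentence
  for (k in trait$required)
    if (!any(keyword_match(sents, k))) return("")
  kept <- unique(sents[keep])
  out <- paste(kept, collapse = " ")
  substr(out, 1L, config$truncate_chars)
}

# keras-style normalization: lowercase, replace punctuation (including
# hyphens) with spaces, split on whitespace
.tokenize_words <- function(text) {
  text <- tolower(text)
  text <- gsub("[!\"#$%&()*+,./:;<=>?@^_`{|}~\\[\\]\\\\'-]", " ", text,
               perl = TRUE)
  w <- strsplit(trimws(text), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Fit a frequency-ranked vocabulary
#'
#' Words are case-folded and punctuation-stripped, then ranked by corpus
#' frequency: the most frequent word gets index 1, ties broken by first
#' occurrence in the corpus. Only words with index `< num_words` are usable
#' by [tokenize_text()]; rarer words are out-of-vocabulary and silently
#' dropped at tokenization time. Index 0 never denotes a word — it is
#' reserved for padding.
#'
#' @param texts Character vector of (training) texts.
#' @param num_words Vocabulary bound.
#' @return An object of class `trait_vocabulary`.
#' @export
fit_vocabulary <- function(texts, num_words = 3000L) {
  stopifnot(is.character(texts), num_words >= 2)
  words <- unlist(lapply(texts, .tokenize_words), use.names = FALSE)
  if (length(words) == 0L)
    stop("cannot fit a vocabulary: no words in `texts`", call. = FALSE)
  first_seen <- !duplicated(words)
  counts <- table(factor(words, levels = words[first_seen]))
  ord <- order(-as.integer(counts))  # stable: ties keep first-seen order
  ranked <- names(counts)[ord]
  structure(list(word_index = stats::setNames(seq_along(ranked), ranked),
                 num_words = as.integer(num_words)),
            class = "trait_vocabulary")
}

#' @export
print.trait_vocabulary <- function(x, ...) {
  cat("<trait_vocabulary> ", length(x$word_index), " distinct words, ",
      "num_words = ", x$num_words,
      " (usable indices 1..", min(x$num_words - 1L, length(x$word_index)),
      ")\n", sep = "")
  invisible(x)
}

#' Tokenize text against a fitted vocabulary
#'
#' @param text A single string (`tokenize_text`) or character vector
#'   (`tokenize_texts`).
#' @param vocab A [fit_vocabulary()] result.
#' @return Integer vector of token indices, all `< num_words`; words that
#'   are out of vocabulary or ranked at or beyond `num_words` are dropped.
#'   May be empty.
#' @export
tokenize_text <- function(text, vocab) {
  stopifnot(inherits(vocab, "trait_vocabulary"))
  idx <- unname(vocab$word_index[.tokenize_words(text)])
  as.integer(idx[!is.na(idx) & idx < vocab$num_words])
}

#' @rdname tokenize_text
#' @export
tokenize_texts <- function(text, vocab) {
  lapply(text, tokenize_text, vocab = vocab)
}

#' Pad token sequences into a rectangular batch
#'
#' Right-pads with index 0 up to the longest sequence in the batch, or to
#' `max_len` if given (longer sequences are tail-truncated). Returns the
#' integer matrix and the padding mask.
#'
#' @param sequences List of integer vectors from [tokenize_texts()].
#' @param max_len Optional length cap.
#' @return List with `tokens` (n x L integer matrix) and `mask` (logical
#'   matrix, `TRUE` where a real token sits).
#' @export
pad_batch <- function(sequences, max_len = NULL) {
  stopifnot(is.list(sequences), length(sequences) > 0L)
  lens <- lengths(sequences)
  L <- if (is.null(max_len)) max(lens, 1L) else as.integer(max_len)
  stopifnot(L >= 1L)
  tok <- matrix(0L, nrow = length(sequences), ncol = L)
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (length(s) > L) s <- s[seq_len(L)]
    if (length(s)) tok[i, seq_along(s)] <- s
  }
  list(tokens = tok, mask = tok != 0L)
}

#' Serialize and restore tokenizer state
#'
#' The fitted vocabulary (word-to-index map and `num_words` bound) is
#' written as JSON so that a prediction run can tokenize new text exactly as
#' the training run did.
#'
#' @param vocab A `trait_vocabulary`.
#' @param path JSON file path.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "trait_vocabulary"))
  jsonlite::write_json(
    list(word_index = as.list(vocab$word_index),
         num_words = vocab$num_words),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(word_index = stats::setNames(
                   as.integer(unlist(x$word_index)), names(x$word_index)),
                 num_words = as.integer(x$num_words)),
            class = "trait_vocabulary")
}

# stable fingerprint used to detect tokenizer mismatch at prediction time
.vocab_hash <- function(vocab) {
  key <- paste(names(vocab$word_index), vocab$word_index,
               collapse = ";", sep = ":")
  sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1)) %% 2147483647 +
    vocab$num_words
}
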