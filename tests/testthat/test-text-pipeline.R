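test_that("sentences split at terminal punctuation plus whitespace", {
  expect_identical(split_sentences("A. B! C?"), c("A.", "B!", "C?"))
  expect_identical(split_sentences("No terminal punctuation"),
                   "No terminal punctuation")
  expect_identical(split_sentences("Grows at 37 C. Ferments glucose."),
                   c("Grows at 37 C.", "Ferments glucose."))
  expect_identical(split_sentences("One. trailing fragment"),
                   c("One.", "trailing fragment"))
  expect_length(split_sentences(""), 0L)
})

test_that("winnowing keeps keyword sentences, gated on required keywords", {
  cfg <- text_prep_config()
  t1 <- trait_fermentation()
  expect_identical(
    winnow("Rods. Ferments glucose. Motile.", t1, cfg),
    "Ferments glucose.")

  # no "ferment" sentence at all: everything is discarded
  t2 <- trait_acetate()
  expect_identical(winnow("Produces acetate. Motile rods.", t2, cfg), "")

  # acetate sentence kept only because a ferment sentence opens the gate
  expect_identical(
    winnow("Ferments sugars. Produces acetate. Motile.", t2, cfg),
    "Ferments sugars. Produces acetate.")

  # duplicated sentences are discarded, first occurrence kept
  expect_identical(
    winnow("Ferments glucose. Motile. Ferments glucose.", t1, cfg),
    "Ferments glucose.")

  expect_identical(winnow("", t1, cfg), "")
})

test_that("winnowed text is truncated at the character budget", {
  long_sentence <- paste0("Ferments ", strcat_n("glucose ", 4000), "slowly.")
  expect_gt(nchar(long_sentence), 25000)
  out <- winnow(long_sentence, trait_fermentation(), text_prep_config())
  expect_equal(nchar(out), 25000L)

  # full-text mode carries the larger budget and vocabulary
  full <- text_prep_config(mode = "full_text")
  expect_equal(full$truncate_chars, 200000L)
  expect_equal(full$num_words, 5000L)
})

test_that("winnowing is idempotent", {
  cfg <- text_prep_config()
  texts <- c(
    "Ferments glucose. Motile rods. Non-fermentative forms absent.",
    "Rods. Sugars are fermented to lactate! Grows at 30 C.",
    "Non-fermentative. Catalase-positive.")
  for (tr in list(trait_fermentation(), trait_acetate()))
    for (x in texts) {
      once <- winnow(x, tr, cfg)
      expect_identical(winnow(once, tr, cfg), once)
    }
})

test_that("vocabulary ranks by frequency with first-occurrence tie-break", {
  v <- fit_vocabulary("a a b", num_words = 10)
  expect_equal(unname(v$word_index[c("a", "b")]), c(1L, 2L))

  # tie between b and c resolved by first occurrence
  v2 <- fit_vocabulary(c("c b a", "a b c", "a"), num_words = 10)
  expect_equal(unname(v2$word_index[c("a", "c", "b")]), c(1L, 2L, 3L))

  # case-folding and punctuation stripping: hyphens split words here
  v3 <- fit_vocabulary("Non-fermentative, rods. RODS!", num_words = 10)
  expect_equal(unname(v3$word_index[c("rods", "non", "fermentative")]),
               c(1L, 2L, 3L))
  expect_error(fit_vocabulary(c("", "  ")), "no words")
})

test_that("tokenization drops OOV and over-bound words; 0 is padding only", {
  v <- fit_vocabulary("a a a b b c", num_words = 3)  # usable: a=1, b=2
  expect_identical(tokenize_text("a b a", v), c(1L, 2L, 1L))
  expect_identical(tokenize_text("c c zz", v), integer(0))  # c ranked 3 >= bound
  expect_identical(tokenize_text("A b", v), c(1L, 2L))
  expect_true(all(unlist(tokenize_texts(c("a b c", "b a"), v)) < v$num_words))
  expect_true(all(unlist(tokenize_texts(c("a b c", "b a"), v)) > 0L))
})

test_that("evaluation-only words never enter a train-fitted vocabulary", {
  train <- c("ferments glucose slowly", "non fermentative rods")
  eval_only <- "xylanolytic archaeon"
  v <- fit_vocabulary(train, num_words = 100)
  expect_false(any(c("xylanolytic", "archaeon") %in% names(v$word_index)))
  expect_identical(tokenize_text(eval_only, v), integer(0))
})

test_that("padding right-pads with zero and can cap length", {
  p <- pad_batch(list(1L, c(1L, 2L)))
  expect_identical(p$tokens, matrix(c(1L, 1L, 0L, 2L), nrow = 2))
  expect_identical(p$mask, p$tokens != 0L)

  same <- pad_batch(list(c(1L, 2L), c(3L, 4L)))
  expect_identical(same$tokens, matrix(c(1L, 3L, 2L, 4L), nrow = 2))

  capped <- pad_batch(list(c(1L, 2L, 3L, 4L)), max_len = 2)
  expect_identical(capped$tokens, matrix(c(1L, 2L), nrow = 1))

  empty <- pad_batch(list(integer(0)))
  expect_identical(empty$tokens, matrix(0L, 1, 1))
})

test_that("tokenizer state serializes to JSON and back", {
  d <- withr::local_tempdir()
  v <- fit_vocabulary(c("ferments glucose", "non fermentative"), 50)
  f <- file.path(d, "vocab.json")
  write_vocabulary(v, f)
  v2 <- read_vocabulary(f)
  expect_identical(v2$word_index, v$word_index)
  expect_identical(v2$num_words, v$num_words)
  expect_identical(tokenize_text("ferments non", v2),
                   tokenize_text("ferments non", v))
})
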