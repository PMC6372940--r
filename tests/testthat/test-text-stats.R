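test_that("tokenization splits sentences and words as specified", {
  t1 <- tokenize_text("Hello. World.")
  expect_length(t1$sentences, 2L)
  expect_equal(t1$words, c("hello", "world"))
  t0 <- tokenize_text("")
  expect_length(t0$sentences, 0L)
  expect_length(t0$words, 0L)
  expect_equal(t0$char_count, 0L)
  # decimal points are not sentence boundaries
  expect_length(tokenize_text("It weighs 3.5 kilos today")$sentences, 1L)
  # colons and semicolons are boundaries
  expect_length(tokenize_text("First part: second part; third part.")$sentences, 3L)
})

test_that("the abbreviation list suppresses false sentence boundaries", {
  t <- tokenize_text("Dr. Smith left")
  expect_length(t$sentences, 1L)
  expect_equal(t$words, c("dr", "smith", "left"))
  expect_length(tokenize_text("Use aspirin, e.g. for headaches, daily.")$sentences, 1L)
  # a real boundary after a non-abbreviation still splits
  expect_length(tokenize_text("He left. She stayed.")$sentences, 2L)
})

test_that("syllable counting uses the dictionary with a vowel-group fallback", {
  expect_equal(count_syllables("cat"), 1L)
  expect_equal(count_syllables("understandability"), 7L)  # dictionary entry
  expect_gte(count_syllables("rhythm"), 1L)               # minimum-1 floor
  expect_equal(count_syllables("made"), 1L)               # silent e via dictionary
  expect_equal(count_syllables(c("doctor", "hospital")), c(2L, 3L))
  expect_error(count_syllables(""), "non-empty")
})

test_that("surface counts cover the raw readability components", {
  tok <- tokenize_text("The cat sat on the mat. It was happy.")
  sc <- surface_counts(tok)
  expect_equal(sc$words, 9L)
  expect_equal(sc$sentences, 2L)
  expect_equal(sc$characters, 27L)
  expect_equal(sc$syllables, 10L)
  expect_equal(sc$polysyllable_words, 0L)
  # difficult words: absent from the common list
  tok2 <- structure(list(sentences = list(c("a", "be")), words = c("a", "be"),
                         char_count = 3L, letter_count = 3L),
                    class = "tokenized_text")
  expect_equal(surface_counts(tok2, common_words = c("a", "be"))$difficult_words, 0L)
  tok3 <- structure(list(sentences = list("xyzzy"), words = "xyzzy",
                         char_count = 5L, letter_count = 5L),
                    class = "tokenized_text")
  expect_equal(surface_counts(tok3, common_words = c("a"))$difficult_words, 1L)
})

test_that("long-word counts are monotone in the length threshold", {
  for (seed in 1:10) {
    set.seed(seed)
    words <- replicate(40, paste(sample(letters, sample(1:16, 1),
                                        replace = TRUE), collapse = ""))
    tok <- tokenize_text(paste(paste(words, collapse = " "), "."))
    sc <- surface_counts(tok)
    expect_lte(sc$words_longer_than_13, sc$words_longer_than_10)
    expect_lte(sc$words_longer_than_10, sc$words_longer_than_6)
    expect_lte(sc$words_longer_than_6, sc$words_longer_than_4)
    expect_lte(sc$polysyllable_words, sc$words)
    expect_lte(sc$difficult_words, sc$words)
  }
})

test_that("readability formulae match direct substitutions", {
  # words/sentences = 1 and syllables/words = 1 puts FRE at its ceiling
  c1 <- list(characters = 3, letters = 3, words = 1, sentences = 1,
             syllables = 1, polysyllable_words = 0, difficult_words = 0,
             words_longer_than_6 = 0)
  expect_equal(readability_scores(c1)[["fre"]], 121.22, tolerance = 1e-12)
  # 20 words, 2 sentences, 5 words > 6 chars
  c2 <- list(characters = 80, letters = 80, words = 20, sentences = 2,
             syllables = 28, polysyllable_words = 0, difficult_words = 0,
             words_longer_than_6 = 5)
  expect_equal(readability_scores(c2)[["lix"]], 35.0, tolerance = 1e-12)
  # 30 sentences, 30 polysyllables
  c3 <- list(characters = 500, letters = 500, words = 150, sentences = 30,
             syllables = 300, polysyllable_words = 30, difficult_words = 10,
             words_longer_than_6 = 30)
  expect_equal(readability_scores(c3)[["smog"]],
               1.0430 * sqrt(30) + 3.1291, tolerance = 1e-12)
  expect_error(readability_scores(list(words = 0, sentences = 1)), "at least 1")
})

test_that("FRE falls and SMOG rises with harder surface statistics", {
  base <- list(characters = 100, letters = 100, words = 20, sentences = 2,
               syllables = 24, polysyllable_words = 1, difficult_words = 4,
               words_longer_than_6 = 5)
  fre <- sapply(seq(24, 60, by = 4), function(sy) {
    b <- base; b$syllables <- sy; readability_scores(b)[["fre"]]
  })
  expect_true(all(diff(fre) < 0))
  smog <- sapply(0:10, function(po) {
    b <- base; b$polysyllable_words <- po; readability_scores(b)[["smog"]]
  })
  expect_true(all(diff(smog) >= 0))
})

test_that("duplicating a document leaves every formula unchanged", {
  text <- "Doctors recommend drinking water every day. Hydration helps the body function well."
  one <- readability_scores(surface_counts(tokenize_text(text)))
  two <- readability_scores(surface_counts(tokenize_text(paste(text, text))))
  expect_equal(one, two, tolerance = 1e-12)
})

test_that("normalize_features emits raw, per-word and per-sentence variants", {
  out <- normalize_features(c(x = 10), words = 5, sentences = 2)
  expect_equal(out, c(x = 10, x_per_word = 2, x_per_sentence = 5))
  z <- normalize_features(c(x = 0), words = 5, sentences = 2)
  expect_true(all(z == 0))
  # round trip: f_per_word * words recovers f
  set.seed(1)
  raw <- setNames(runif(6, 0, 50), paste0("f", 1:6))
  out2 <- normalize_features(raw, words = 7, sentences = 3)
  expect_equal(unname(out2[paste0(names(raw), "_per_word")] * 7), unname(raw))
  # zero denominators give missing variants, raw kept
  out3 <- normalize_features(c(x = 2), words = 0, sentences = 0)
  expect_equal(unname(out3[["x"]]), 2)
  expect_true(is.na(out3[["x_per_word"]]) && is.na(out3[["x_per_sentence"]]))
})
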