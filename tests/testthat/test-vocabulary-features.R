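test_that("affix and dictionary counts use case-folded keyword matching", {
  out <- affix_and_dictionary_counts("angiogram",
                                     prefixes = c("amni", "angi"),
                                     suffixes = c("algia"),
                                     acronyms = c("mri"),
                                     dictionaries = list(icd = "asthma"))
  expect_equal(unname(out["medical_prefix_words"]), 1)
  empty <- affix_and_dictionary_counts(character())
  expect_true(all(empty == 0))
  # planted drug names are recovered from the bundled drug dictionary
  drugs <- rr_resources()$dictionaries$drugbank[1:3]
  words <- c("take", drugs, "daily")
  out2 <- affix_and_dictionary_counts(words)
  expect_equal(unname(out2["dict_drugbank_words"]), 3)
  # suffix: neuralgia ends with -algia
  out3 <- affix_and_dictionary_counts("neuralgia")
  expect_gte(unname(out3["medical_suffix_words"]), 1)
})

test_that("concept matching is greedy longest-match without overlaps", {
  lex <- lexicon(c("heart", "heart attack"))
  m <- match_concepts(c("a", "heart", "attack"), lex)
  expect_equal(m$term, "heart attack")
  expect_equal(m$start, 1L)
  expect_equal(m$end, 3L)
  expect_equal(nrow(match_concepts(c("no", "terms", "here"), lex)), 0L)
  lex2 <- lexicon(c("chest pain", "angina"))
  m2 <- match_concepts(c("chest", "pain", "and", "angina"), lex2)
  expect_equal(m2$term, c("chest pain", "angina"))
  expect_equal(m2$start, c(0L, 3L))
})

# exhaustive non-overlapping longest-match oracle for short documents
brute_match <- function(words, terms) {
  out <- list(); i <- 1L; n <- length(words)
  while (i <= n) {
    best <- NULL
    for (l in seq(n - i + 1L, 1L)) {        # longest span first
      span <- paste(words[i:(i + l - 1L)], collapse = " ")
      if (span %in% terms) { best <- list(term = span, len = l); break }
    }
    if (is.null(best)) i <- i + 1L
    else { out[[length(out) + 1L]] <- best$term; i <- i + best$len }
  }
  if (length(out)) unlist(out) else character()
}

test_that("matcher agrees with an exhaustive all-span oracle on short docs", {
  res <- rr_resources()
  vocabterms <- res$chv$entries$term
  word_pool <- unique(c(unlist(strsplit(vocabterms, " ")), "the", "of",
                        "patient", "felt", "a", "sudden"))
  for (seed in 1:20) {
    set.seed(seed)
    words <- sample(word_pool, sample(5:40, 1), replace = TRUE)
    got <- match_concepts(words, res$chv)$term
    expect_equal(got, brute_match(words, vocabterms))
  }
})

test_that("equal-length candidates at one position break ties lexicographically", {
  lex <- lexicon(c("zeta pain", "beta pain"))
  # both could start at offset 0 only if first words equal; force a true tie
  lex2 <- lexicon(c("pain zz", "pain aa"))
  m <- match_concepts(c("pain", "aa"), lex2)
  expect_equal(m$term, "pain aa")
})

test_that("consumer-vocabulary features average scores with missing empty subsets", {
  m <- data.frame(term = c("x", "y"), start = c(0L, 2L), end = c(1L, 3L),
                  score = c(0.23, 0.78), group = c("symptom", "symptom"))
  f <- chv_features(m)
  expect_equal(unname(f["chv_score_mean"]), 0.505)
  expect_equal(unname(f["chv_count"]), 2)
  expect_equal(unname(f["chv_symptom_score_mean"]), 0.505)
  expect_true(is.na(f["chv_disease_score_mean"]))
  expect_equal(unname(f["chv_disease_count"]), 0)
  e <- chv_features(match_concepts(character(), lexicon("pain")))
  expect_equal(unname(e["chv_count"]), 0)
  expect_true(is.na(e["chv_score_mean"]))
})

test_that("expert-vocabulary features average tree depth by group", {
  tab <- data.frame(term = c("pain", "stroke"), depth = c(2L, 6L),
                    group = c("symptom", "disease"))
  m <- data.frame(term = c("pain", "stroke"), start = c(0L, 1L),
                  end = c(1L, 2L), score = NA_real_,
                  group = NA_character_)
  f <- mesh_features(m, tab)
  expect_equal(unname(f["mesh_tree_depth_mean"]), 4)
  expect_equal(unname(f["mesh_count"]), 2)
  expect_equal(unname(f["mesh_symptom_tree_depth_mean"]), 2)
  expect_equal(unname(f["mesh_disease_tree_depth_mean"]), 6)
  # unresolvable terms are skipped with a message
  m2 <- rbind(m, data.frame(term = "unknownium", start = 2L, end = 3L,
                            score = NA_real_, group = NA_character_))
  expect_message(f2 <- mesh_features(m2, tab), "skipping")
  expect_equal(unname(f2["mesh_count"]), 2)
})

test_that("duplicating a document doubles counts and preserves means", {
  res <- rr_resources()
  words <- c("the", "patient", "reported", "chest", "pain", "and", "angina",
             "after", "a", "heart", "attack")
  m1 <- match_concepts(words, res$chv)
  m2 <- match_concepts(c(words, words), res$chv)
  f1 <- chv_features(m1); f2 <- chv_features(m2)
  expect_equal(unname(f2["chv_count"]), 2 * unname(f1["chv_count"]))
  expect_equal(unname(f2["chv_score_mean"]), unname(f1["chv_score_mean"]))
  a1 <- affix_and_dictionary_counts(words)
  a2 <- affix_and_dictionary_counts(c(words, words))
  expect_equal(unname(a2), 2 * unname(a1))
})

test_that("lexicon I/O round-trips through the TSV format", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("term\tscore\tgroup", "Chest  Pain\t0.5\tsymptom",
               "angina\t0.2\tdisease"), path)
  lex <- read_lexicon(path)
  expect_equal(lex$entries$term, c("chest pain", "angina"))
  expect_equal(lex$entries$score, c(0.5, 0.2))
})
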