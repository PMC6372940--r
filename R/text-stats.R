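#' @title Tokenization, syllables and readability formulae
#' @description
#' The surface statistics underlying traditional readability formulae:
#' sentence and word tokenization, syllable counting (dictionary lookup with
#' a vowel-group fallback), the raw component counts (characters, words,
#' sentences, syllables, polysyllables, difficult words, long words), and
#' the eight classic formulae ARI, CLI, DCI, FKGL, FRE, GFI, LIX and SMOG.
#' @name text_stats
NULL

#' Tokenize text into sentences and words
#'
#' Sentences are split on terminal punctuation (`.`, `!`, `?`, `:`, `;`)
#' followed by whitespace or end of text; a small abbreviation list (Dr.,
#' Mr., e.g., i.e., ...) suppresses false boundaries. Words are maximal
#' alphanumeric-plus-apostrophe runs, lowercased.
#'
#' @param text a length-1 character string.
#' @param abbreviations character vector of abbreviations (with their
#'   periods, e.g. `"dr."`); defaults to the bundled list.
#' @return an object of class `tokenized_text`: list with `sentences` (list
#'   of word vectors), `words` (flattened), `char_count` (letters+digits)
#'   and `letter_count` (letters only).
#' @examples
#' tokenize_text("Hello. World.")$sentences
#' @export
tokenize_text <- function(text, abbreviations = rr_resources()$abbreviations) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- structure(list(sentences = list(), words = character(),
                          char_count = 0L, letter_count = 0L),
                     class = "tokenized_text")
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  protected <- text
  # shield abbreviation periods with a one-dot-leader placeholder
  for (ab in abbreviations) {
    pat <- paste0("(?i)(?<![A-Za-z])",
                  gsub(".", "\\.", ab, fixed = TRUE))
    rep <- gsub(".", "\u2024", ab, fixed = TRUE)
    protected <- gsub(pat, rep, protected, perl = TRUE)
  }
  raw_sent <- strsplit(protected, "[.!?:;]+(\\s+|$)", perl = TRUE)[[1]]
  raw_sent <- raw_sent[nzchar(trimws(raw_sent))]
  sentences <- lapply(raw_sent, function(s) {
    s <- gsub("\u2024", ".", s, fixed = TRUE)
    w <- regmatches(s, gregexpr("[A-Za-z0-9']+", s))[[1]]
    w <- tolower(gsub("^'+|'+$", "", w))
    w[nzchar(w)]
  })
  sentences <- sentences[lengths(sentences) > 0L]
  words <- unlist(sentences, use.names = FALSE)
  if (is.null(words)) words <- character()
  joined <- paste(words, collapse = "")
  structure(list(
    sentences = sentences,
    words = words,
    char_count = nchar(gsub("[^a-z0-9]", "", joined)),
    letter_count = nchar(gsub("[^a-z]", "", joined))
  ), class = "tokenized_text")
}

#' @export
print.tokenized_text <- function(x, ...) {
  cat(sprintf("<tokenized_text: %d sentences, %d words>\n",
              length(x$sentences), length(x$words)))
  invisible(x)
}

#' Count syllables in words
#'
#' Uses the bundled syllable dictionary when the word is covered (this
#' handles silent-e words and other irregulars); otherwise falls back to the
#' number of vowel groups (`a e i o u y`), floored at 1.
#'
#' @param words character vector of non-empty words.
#' @param dict optional named integer vector `word -> syllables`.
#' @return integer vector of syllable counts.
#' @examples
#' count_syllables(c("cat", "understandability"))
#' @export
count_syllables <- function(words, dict = rr_resources()$syllable_dict) {
  if (length(words) == 0L) return(integer())
  if (!is.character(words) || anyNA(words) || any(!nzchar(words)))
    stop("count_syllables() requires non-empty character words")
  w <- tolower(words)
  out <- unname(dict[w])
  miss <- is.na(out)
  if (any(miss)) {
    groups <- lengths(regmatches(w[miss], gregexpr("[aeiouy]+", w[miss])))
    out[miss] <- pmax(groups, 1L)
  }
  as.integer(out)
}

#' Raw readability component counts
#'
#' Computes the building blocks of the readability formulae for a tokenized
#' document: characters (letters+digits), letters, words, sentences,
#' syllables, polysyllable words (more than 3 syllables), difficult words
#' (absent from a common-word list, case-folded), and the number of words
#' longer than 4, 6, 10 and 13 characters.
#'
#' @param tok a [tokenize_text()] result.
#' @param common_words character vector of common words (Dale-Chall-style);
#'   defaults to the bundled fixture list.
#' @return an object of class `surface_counts` (a named list of counts).
#' @export
surface_counts <- function(tok, common_words = rr_resources()$common_words) {
  stopifnot(inherits(tok, "tokenized_text"))
  if (length(common_words) == 0L) stop("common_words must be non-empty")
  w <- tok$words
  syl <- if (length(w)) count_syllables(w) else integer()
  nc <- nchar(w)
  structure(list(
    characters = as.integer(tok$char_count),
    letters = as.integer(tok$letter_count),
    words = length(w),
    sentences = length(tok$sentences),
    syllables = as.integer(sum(syl)),
    polysyllable_words = as.integer(sum(syl > 3L)),
    difficult_words = as.integer(sum(!(w %in% common_words))),
    words_longer_than_4 = as.integer(sum(nc > 4L)),
    words_longer_than_6 = as.integer(sum(nc > 6L)),
    words_longer_than_10 = as.integer(sum(nc > 10L)),
    words_longer_than_13 = as.integer(sum(nc > 13L))
  ), class = "surface_counts")
}

#' The eight traditional readability formulae
#'
#' Given surface counts, computes: Automated Readability Index (ARI),
#' Coleman-Liau Index (CLI), Dale-Chall Index (DCI), Flesch-Kincaid Grade
#' Level (FKGL), Flesch Reading Ease (FRE), Gunning Fog Index (GFI),
#' Lasbarhetsindex (LIX) and Simple Measure of Gobbledygook (SMOG). ARI
#' counts alphanumeric characters; CLI counts letters only, following each
#' formula's original definition. Except for FRE (higher = easier), higher
#' scores mean harder text.
#'
#' @param counts a [surface_counts()] result, or a named list with the same
#'   fields.
#' @return named numeric vector with elements `ari`, `cli`, `dci`, `fkgl`,
#'   `fre`, `gfi`, `lix`, `smog`.
#' @export
readability_scores <- function(counts) {
  ch <- counts$characters; le <- counts$letters
  w <- counts$words; s <- counts$sentences
  sy <- counts$syllables; po <- counts$polysyllable_words
  dw <- counts$difficult_words; w6 <- counts$words_longer_than_6
  if (is.null(w) || is.null(s) || w < 1 || s < 1)
    stop("readability_scores() requires at least 1 word and 1 sentence")
  diff_pct <- 100 * dw / w
  dci <- 0.1579 * diff_pct + 0.0496 * (w / s)
  if (diff_pct > 5) dci <- dci + 3.6365
  c(
    ari  = 4.71 * (ch / w) + 0.5 * (w / s) - 21.43,
    cli  = 0.0588 * (100 * le / w) - 0.296 * (100 * s / w) - 15.8,
    dci  = dci,
    fkgl = 0.39 * (w / s) + 11.8 * (sy / w) - 15.59,
    fre  = 206.835 - 1.015 * (w / s) - 84.6 * (sy / w),
    gfi  = 0.4 * ((w / s) + 100 * (po / w)),
    lix  = (w / s) + 100 * (w6 / w),
    smog = 1.0430 * sqrt(po * 30 / s) + 3.1291
  )
}

#' Emit raw, per-word and per-sentence variants of features
#'
#' For every raw feature `f` this emits `f`, `f_per_word = f/words` and
#' `f_per_sentence = f/sentences`. When a denominator is zero the
#' corresponding variant is emitted as `NA` and the raw value kept.
#'
#' @param raw named numeric vector (or list) of raw feature values.
#' @param words,sentences document word and sentence counts.
#' @return named numeric vector three times the length of `raw`.
#' @examples
#' normalize_features(c(x = 10), words = 5, sentences = 2)
#' @export
normalize_features <- function(raw, words, sentences) {
  raw <- unlist(raw)
  if (length(raw) == 0L) return(numeric())
  if (is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("raw features must be named")
  pw <- if (words >= 1) raw / words else rep(NA_real_, length(raw))
  ps <- if (sentences >= 1) raw / sentences else rep(NA_real_, length(raw))
  names(pw) <- paste0(names(raw), "_per_word")
  names(ps) <- paste0(names(raw), "_per_sentence")
  c(raw, pw, ps)
}
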