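#' @title Natural-language and HTML-tag features
#' @description
#' Part-of-speech class counts from a pluggable tagger backend (a bundled
#' deterministic backend uses closed-class word lists and suffix rules),
#' sentiment polarity counts from a word lexicon, stop word and
#' out-of-dictionary counts, and counts of structural HTML tags (headings,
#' lists, images, tables, ...) computed on the raw HTML independently of any
#' extraction pipeline.
#' @name nl_html_features
NULL

.rr_pos_classes <- c("verb", "noun", "pronoun", "adjective", "adverb",
                     "adposition", "conjunction", "determiner", "number",
                     "particle", "other", "punctuation")

.rr_closed_class <- list(
  pronoun = c("i", "me", "my", "mine", "myself", "we", "us", "our", "ours",
              "ourselves", "you", "your", "yours", "yourself", "he", "him",
              "his", "himself", "she", "her", "hers", "herself", "it", "its",
              "itself", "they", "them", "their", "theirs", "themselves",
              "who", "whom", "whose", "someone", "anyone", "everyone",
              "nothing", "something", "anything", "everything"),
  determiner = c("a", "an", "the", "this", "that", "these", "those", "each",
                 "every", "some", "any", "no", "another", "such"),
  adposition = c("in", "on", "at", "by", "for", "with", "about", "against",
                 "between", "into", "through", "during", "before", "after",
                 "above", "below", "to", "from", "up", "down", "of", "over",
                 "under", "near", "without", "within"),
  conjunction = c("and", "or", "but", "nor", "so", "yet", "because",
                  "although", "while", "if", "when", "since", "unless",
                  "whereas"),
  particle = c("not", "n't", "out", "off", "away", "back"),
  verb = c("is", "am", "are", "was", "were", "be", "been", "being", "have",
           "has", "had", "do", "does", "did", "will", "would", "can",
           "could", "shall", "should", "may", "might", "must", "get", "got",
           "go", "went", "gone", "take", "took", "make", "made", "say",
           "said", "feel", "felt", "see", "saw", "seen", "know", "knew"),
  adjective = c("good", "bad", "new", "old", "big", "small", "high", "low",
                "easy", "hard", "sick", "healthy", "chronic", "acute",
                "severe", "mild", "common", "rare")
)

#' The bundled deterministic part-of-speech tagger
#'
#' Returns a tagger backend: a function mapping a word vector to a tag
#' vector over the universal classes (verb, noun, pronoun, adjective,
#' adverb, adposition, conjunction, determiner, number, particle, other,
#' punctuation). Tagging uses closed-class word lists, a numeral pattern and
#' suffix heuristics (`-ly` adverb; `-ing`/`-ed` verb; `-ous`/`-ful`/`-ive`
#' adjective), with noun as the default open-class tag. It supplies neither
#' entity spans nor a parse tree, so those features are emitted as missing;
#' a richer backend can be plugged into [pos_features()].
#'
#' @return a function `words -> tags`, deterministic for fixed input.
#' @export
default_tagger <- function() {
  function(words) {
    w <- tolower(words)
    n <- length(w)
    tags <- rep("noun", n)
    if (n == 0L) return(character())
    tags[grepl("^[0-9]+([.,][0-9]+)*$", w)] <- "number"
    tags[endsWith(w, "ly")] <- "adverb"
    tags[endsWith(w, "ing") | endsWith(w, "ed")] <- "verb"
    tags[endsWith(w, "ous") | endsWith(w, "ful") | endsWith(w, "ive")] <- "adjective"
    for (cls in names(.rr_closed_class)) {
      tags[w %in% .rr_closed_class[[cls]]] <- cls
    }
    tags[!grepl("[a-z0-9]", w)] <- "other"
    tags
  }
}

#' Part-of-speech features
#'
#' Counts of each POS class over the document, plus entity count and POS
#' parse-tree height when the backend supplies them (`NA` otherwise —
#' downstream consumers must tolerate missing features).
#'
#' @param tok a `tokenized_text`.
#' @param tagger a tagger backend (see [default_tagger()]); may attach
#'   attributes `entities` (count) and `tree_height` to its return value.
#' @return named numeric vector `pos_<class>` for each class, plus
#'   `entity_count` and `parse_tree_height`.
#' @export
pos_features <- function(tok, tagger = default_tagger()) {
  words <- if (inherits(tok, "tokenized_text")) tok$words else as.character(tok)
  tags <- tagger(words)
  if (length(tags) != length(words))
    stop("tagger backend returned wrong-length tag vector")
  counts <- vapply(.rr_pos_classes, function(cl) sum(tags == cl), numeric(1))
  names(counts) <- paste0("pos_", .rr_pos_classes)
  ents <- attr(tags, "entities")
  ht <- attr(tags, "tree_height")
  c(counts,
    entity_count = if (is.null(ents)) NA_real_ else as.numeric(ents),
    parse_tree_height = if (is.null(ht)) NA_real_ else as.numeric(ht))
}

#' Read a sentiment polarity lexicon from TSV
#'
#' Expected columns `word` and `polarity` with values `pos`, `neg` or `neu`.
#'
#' @param path TSV path.
#' @return named character vector `word -> polarity`.
#' @export
read_polarity_lexicon <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("word", "polarity") %in% names(d)))
  pol <- match.arg(d$polarity, c("pos", "neg", "neu"), several.ok = TRUE)
  setNames(pol, tolower(d$word))
}

#' Sentiment polarity counts
#'
#' Counts positive, negative and neutral words; words absent from the
#' lexicon are not counted. Lay-authored health text (forums, blogs) tends
#' to carry more emotional vocabulary than scientific prose, which is what
#' these features pick up.
#'
#' @param words character vector of (lowercased) words.
#' @param polarity a polarity lexicon (named vector `word -> pos|neg|neu`).
#' @return named numeric vector `positive_words`, `negative_words`,
#'   `neutral_words`.
#' @export
sentiment_counts <- function(words, polarity = rr_resources()$polarity) {
  pol <- polarity[tolower(words)]
  c(positive_words = sum(pol == "pos", na.rm = TRUE),
    negative_words = sum(pol == "neg", na.rm = TRUE),
    neutral_words = sum(pol == "neu", na.rm = TRUE))
}

#' Stop word and out-of-dictionary counts
#'
#' @param words character vector of (lowercased) words.
#' @param english_vocab non-empty word set standing in for a standard
#'   English dictionary.
#' @param stoplist non-empty stop word list.
#' @return named numeric vector `stopword_count`, `oov_count`.
#' @export
lexical_membership_counts <- function(words,
                                      english_vocab = rr_resources()$english_vocab,
                                      stoplist = rr_resources()$stopwords) {
  if (length(english_vocab) == 0L || length(stoplist) == 0L)
    stop("english_vocab and stoplist must be non-empty")
  w <- tolower(words)
  c(stopword_count = sum(w %in% stoplist),
    oov_count = sum(!(w %in% english_vocab)))
}

.rr_html_tags <- c("abbr", "a", "blockquote", "b", "cite", "div", "form",
                   "h1", "h2", "h3", "h4", "h5", "h6", "img", "input",
                   "link", "dl", "ul", "ol", "q", "script", "span",
                   "table", "p")

#' Structural HTML tag counts
#'
#' Counts occurrences of a fixed set of HTML tags on the raw HTML (never on
#' extracted text, so the values are independent of any extraction
#' pipeline), plus the derived totals `headings_total` (h1-h6) and
#' `lists_total` (dl+ul+ol). Malformed HTML is parsed best-effort.
#'
#' @param html raw HTML string.
#' @return named numeric vector `tag_<name>` for each tag plus
#'   `headings_total` and `lists_total`.
#' @examples
#' html_tag_features("<dl></dl><ul></ul><ol></ol>")[["lists_total"]]
#' @export
html_tag_features <- function(html) {
  zero <- setNames(numeric(length(.rr_html_tags)),
                   paste0("tag_", .rr_html_tags))
  counts <- zero
  if (length(html) == 1L && !is.na(html) && nzchar(trimws(html))) {
    doc <- tryCatch(xml2::read_html(html, encoding = "UTF-8"),
                    error = function(e) NULL)
    if (!is.null(doc)) {
      for (tg in .rr_html_tags) {
        counts[paste0("tag_", tg)] <-
          length(xml2::xml_find_all(doc, paste0("//", tg)))
      }
    }
  }
  c(counts,
    headings_total = sum(counts[paste0("tag_", c("h1", "h2", "h3", "h4", "h5", "h6"))]),
    lists_total = sum(counts[paste0("tag_", c("dl", "ul", "ol"))]))
}
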