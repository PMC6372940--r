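#' @title Medical-vocabulary features
#' @description
#' Features driven by medical lexical resources: affix and keyword-dictionary
#' counts (general medical vocabularies), scored consumer-vocabulary concept
#' matches (CHV-style) and hierarchical expert-vocabulary matches
#' (MeSH-style, where tree depth proxies concept difficulty). Concept
#' mapping is a deterministic greedy longest-match dictionary lookup over the
#' token stream; a different concept-mapper backend can be substituted by
#' supplying matches in the same shape.
#' @name vocabulary_features
NULL

#' Read a scored lexicon from TSV
#'
#' Expected columns: `term` (required; multiword terms allowed), `score`
#' (optional real), `group` (optional, e.g. `symptom` / `disease` /
#' `other`). Terms are case-folded and whitespace-normalized.
#'
#' @param path TSV file path (with header).
#' @param name lexicon name (defaults to the file name).
#' @return an object of class `rr_lexicon`: list with `name` and `entries`
#'   (data frame `term`, `score`, `group`).
#' @export
read_lexicon <- function(path, name = basename(path)) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"term" %in% names(d)) stop("lexicon file needs a 'term' column")
  lexicon(d$term,
          scores = if ("score" %in% names(d)) d$score else NULL,
          groups = if ("group" %in% names(d)) d$group else NULL,
          name = name)
}

#' Construct a lexicon in memory
#'
#' @param terms character vector of terms (multiword allowed).
#' @param scores optional numeric difficulty/familiarity scores.
#' @param groups optional character groups (`symptom`, `disease`, `other`).
#' @param name lexicon name.
#' @return an `rr_lexicon` object.
#' @export
lexicon <- function(terms, scores = NULL, groups = NULL, name = "lexicon") {
  term <- trimws(gsub("\\s+", " ", tolower(terms)))
  if (any(!nzchar(term))) stop("empty lexicon term")
  if (!is.null(scores) && any(!is.finite(scores[!is.na(scores)])))
    stop("lexicon scores must be finite")
  entries <- data.frame(
    term = term,
    score = if (is.null(scores)) NA_real_ else as.numeric(scores),
    group = if (is.null(groups)) NA_character_ else as.character(groups),
    stringsAsFactors = FALSE
  )
  entries <- entries[!duplicated(entries$term), , drop = FALSE]
  structure(list(name = name, entries = entries), class = "rr_lexicon")
}

#' Read a concept table (term, tree depth, group) from TSV
#'
#' @param path TSV with header columns `term`, `depth`, `group`.
#' @return data frame with case-folded `term`, integer `depth` (>= 1) and
#'   `group`.
#' @export
read_concept_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("term", "depth") %in% names(d)))
  d$term <- trimws(gsub("\\s+", " ", tolower(d$term)))
  d$depth <- as.integer(d$depth)
  if (any(d$depth < 1L)) stop("concept tree depth must be >= 1")
  if (!"group" %in% names(d)) d$group <- NA_character_
  d[!duplicated(d$term), c("term", "depth", "group")]
}

#' Affix, acronym and keyword-dictionary counts
#'
#' Counts words beginning with a medical (Latin/Greek) prefix, ending with a
#' medical suffix, appearing in an acronym list, and appearing in each of a
#' set of named keyword dictionaries (e.g. ICD-style disease terms, drug
#' names, a medical spelling dictionary). Matching is simple case-folded
#' keyword matching; a word counts at most once per feature.
#'
#' @param words character vector of (lowercased) words.
#' @param prefixes,suffixes non-empty character vectors of affixes.
#' @param acronyms character vector of acronyms (case-insensitive).
#' @param dictionaries named list of word sets.
#' @return named numeric vector: `medical_prefix_words`,
#'   `medical_suffix_words`, `acronym_words`, then `dict_<name>_words` per
#'   dictionary.
#' @export
affix_and_dictionary_counts <- function(words,
                                        prefixes = rr_resources()$prefixes,
                                        suffixes = rr_resources()$suffixes,
                                        acronyms = rr_resources()$acronyms,
                                        dictionaries = rr_resources()$dictionaries) {
  if (length(prefixes) == 0L || length(suffixes) == 0L)
    stop("affix lists must be non-empty")
  w <- tolower(words)
  has_prefix <- function(word) any(startsWith(word, prefixes) & nchar(word) > nchar(prefixes))
  has_suffix <- function(word) any(endsWith(word, suffixes) & nchar(word) > nchar(suffixes))
  out <- c(
    medical_prefix_words = if (length(w)) sum(vapply(w, has_prefix, logical(1))) else 0,
    medical_suffix_words = if (length(w)) sum(vapply(w, has_suffix, logical(1))) else 0,
    acronym_words = sum(w %in% tolower(acronyms))
  )
  for (nm in names(dictionaries)) {
    out[paste0("dict_", nm, "_words")] <- sum(w %in% tolower(dictionaries[[nm]]))
  }
  out
}

#' Match lexicon concepts in a token stream
#'
#' Deterministic greedy longest-match, left to right, case-insensitive.
#' Matched spans are consumed, so matches never overlap; when two
#' equal-length lexicon terms could match at the same position the
#' lexicographically smallest wins.
#'
#' @param tok a `tokenized_text` or a character vector of words.
#' @param lex an `rr_lexicon`.
#' @return data frame with one row per match: `term`, `start`, `end`
#'   (0-based, half-open token offsets), `score`, `group`.
#' @examples
#' lex <- lexicon(c("heart", "heart attack"))
#' match_concepts(c("a", "heart", "attack"), lex)
#' @export
match_concepts <- function(tok, lex) {
  stopifnot(inherits(lex, "rr_lexicon"))
  words <- if (inherits(tok, "tokenized_text")) tok$words else tolower(tok)
  n <- length(words)
  empty <- data.frame(term = character(), start = integer(), end = integer(),
                      score = numeric(), group = character(),
                      stringsAsFactors = FALSE)
  if (n == 0L || nrow(lex$entries) == 0L) return(empty)
  entry_tokens <- strsplit(lex$entries$term, " ", fixed = TRUE)
  len <- lengths(entry_tokens)
  max_len <- max(len)
  # index lexicon entries by (first word, length)
  key <- paste(vapply(entry_tokens, `[[`, "", 1L), len)
  by_key <- split(seq_len(nrow(lex$entries)), key)
  res <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (l in seq(min(max_len, n - i + 1L), 1L)) {
      k <- paste(words[i], l)
      cand <- by_key[[k]]
      if (is.null(cand)) next
      span <- paste(words[i:(i + l - 1L)], collapse = " ")
      hit <- cand[lex$entries$term[cand] == span]
      if (length(hit) > 0L) {
        hit <- hit[order(lex$entries$term[hit])][1L]
        res[[length(res) + 1L]] <- data.frame(
          term = lex$entries$term[hit],
          start = i - 1L, end = i - 1L + l,
          score = lex$entries$score[hit],
          group = lex$entries$group[hit],
          stringsAsFactors = FALSE
        )
        i <- i + l
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.rr_subset_stats <- function(matches, value, prefix, subsets = c("symptom", "disease")) {
  out <- c(sum = nrow(matches),
           mean = if (nrow(matches) > 0L) mean(value) else NA_real_)
  names(out) <- paste0(prefix, c("_count", "_mean"))
  for (g in subsets) {
    sel <- !is.na(matches$group) & matches$group == g
    v <- value[sel]
    add <- c(sum(sel), if (length(v) > 0L) mean(v) else NA_real_)
    names(add) <- paste0(prefix, "_", g, c("_count", "_mean"))
    out <- c(out, add)
  }
  out
}

#' Consumer-vocabulary (CHV-style) features
#'
#' Mean concept score and concept counts over all matches and over the
#' symptom-only and disease-only subsets. Empty subsets yield `NA` means
#' (missing, not zero) so downstream models are not biased.
#'
#' @param matches a [match_concepts()] result from a scored lexicon.
#' @return named numeric vector `chv_count`, `chv_score_mean`,
#'   `chv_symptom_count`, `chv_symptom_score_mean`, `chv_disease_count`,
#'   `chv_disease_score_mean`.
#' @export
chv_features <- function(matches) {
  s <- .rr_subset_stats(matches, matches$score, "chv")
  names(s) <- sub("_mean$", "_score_mean", names(s))
  s
}

#' Expert-vocabulary (MeSH-style) features
#'
#' Concept counts and mean hierarchy tree depth, overall and for symptom /
#' disease subsets. Matches whose term is not present in the concept table
#' are skipped with a message.
#'
#' @param matches a [match_concepts()] result.
#' @param table a concept table from [read_concept_table()].
#' @return named numeric vector `mesh_count`, `mesh_tree_depth_mean` and the
#'   symptom/disease variants.
#' @export
mesh_features <- function(matches, table = rr_resources()$mesh) {
  idx <- match(matches$term, table$term)
  if (anyNA(idx)) {
    message("mesh_features: skipping ", sum(is.na(idx)),
            " match(es) not in the concept table")
    matches <- matches[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  matches$group <- table$group[idx]
  s <- .rr_subset_stats(matches, as.numeric(table$depth[idx]), "mesh")
  names(s) <- sub("_mean$", "_tree_depth_mean", names(s))
  s
}
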