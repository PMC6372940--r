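#' @title Corpus word-frequency rank features
#' @description
#' Builds, for a background corpus, a map from each vocabulary word to a
#' normalized rank value in `[0, 100]`: values close to 100 for the most
#' common words, close to 0 for the rarest. Documents are summarized against
#' one or several such models (typically one per background corpus plus a
#' pooled combined model) by percentiles and means of their per-token rank
#' values; out-of-vocabulary (OV) words are either ignored or counted with
#' value 0, the "maximally rare" reading.
#' @name word_frequency
NULL

.rr_as_token_list <- function(docs) {
  if (is.character(docs)) docs <- as.list(docs)
  lapply(docs, function(d) {
    if (inherits(d, "tokenized_text")) return(d$words)
    d <- as.character(d)
    # a single string is a raw text; a longer vector is already tokenized
    if (length(d) == 1L) tokenize_text(d)$words else tolower(d)
  })
}

#' Build a word-frequency rank model from a corpus
#'
#' Words are sorted by descending total corpus frequency; equal-frequency
#' words share the first position of their tie group (competition ranking),
#' and the word at position `pos` of a vocabulary of size `V` gets value
#' `100 * (V - pos + 1) / V`. The most frequent word therefore always maps
#' to 100 — even when the top frequency is tied — and values weakly
#' decrease with decreasing frequency.
#'
#' @param corpus_docs a non-empty collection of documents: character vector
#'   of texts, list of word vectors, or list of `tokenized_text`.
#' @param name corpus label recorded in the model.
#' @return an object of class `frequency_model`: list with `corpus_name`,
#'   `vocab_size` and `rank_value` (named numeric, word -> value).
#' @examples
#' m <- build_frequency_model(list(c("a", "a", "b")), "toy")
#' m$rank_value  # a -> 100, b -> 50
#' @export
build_frequency_model <- function(corpus_docs, name = "corpus") {
  tokens <- unlist(.rr_as_token_list(corpus_docs), use.names = FALSE)
  if (length(tokens) == 0L) stop("cannot build a frequency model from an empty corpus")
  freq <- sort(table(tokens), decreasing = TRUE)
  v <- length(freq)
  pos <- seq_len(v)
  # equal-frequency words share their tie group's first position
  pos <- stats::ave(pos, as.integer(freq), FUN = min)
  value <- 100 * (v - pos + 1) / v
  structure(list(
    corpus_name = name,
    vocab_size = v,
    rank_value = setNames(as.numeric(value), names(freq))
  ), class = "frequency_model")
}

#' @export
print.frequency_model <- function(x, ...) {
  cat(sprintf("<frequency_model '%s': V = %d>\n", x$corpus_name, x$vocab_size))
  invisible(x)
}

#' Rank-value profile of a document under a frequency model
#'
#' Replaces each document token by its model rank value. With
#' `include_ov = TRUE`, out-of-vocabulary words contribute value 0 and are
#' counted; otherwise they are dropped.
#'
#' @param words character vector of document words (or a `tokenized_text`).
#' @param model a [build_frequency_model()] result.
#' @param include_ov logical, see above.
#' @return an object of class `rank_profile`: list with `values`,
#'   `include_ov`, `ov_count`.
#' @export
rank_profile <- function(words, model, include_ov = FALSE) {
  stopifnot(inherits(model, "frequency_model"))
  if (inherits(words, "tokenized_text")) words <- words$words
  v <- unname(model$rank_value[tolower(words)])
  ov <- sum(is.na(v))
  values <- if (include_ov) ifelse(is.na(v), 0, v) else v[!is.na(v)]
  structure(list(values = as.numeric(values), include_ov = include_ov,
                 ov_count = as.integer(ov)), class = "rank_profile")
}

#' Word-frequency summary features of a rank profile
#'
#' 25th/50th/75th percentiles (linear interpolation between order
#' statistics) and mean of the profile's value multiset. Missing (`NA`) when
#' the profile is empty.
#'
#' @param profile a [rank_profile()] result.
#' @param prefix feature-name prefix, typically the corpus name.
#' @return named numeric vector `<prefix>_p25`, `_p50`, `_p75`, `_mean`.
#' @export
wff_features <- function(profile, prefix = "wff") {
  stopifnot(inherits(profile, "rank_profile"))
  v <- profile$values
  out <- if (length(v) == 0L) rep(NA_real_, 4L)
         else c(unname(quantile(v, c(0.25, 0.5, 0.75), type = 7)), mean(v))
  setNames(out, paste0(prefix, c("_p25", "_p50", "_p75", "_mean")))
}

#' Full word-frequency feature set over several models
#'
#' For each model: the percentile/mean features with OV words ignored, plus
#' the mean including OV words (value 0). Model names are used as feature
#' prefixes.
#'
#' @param words document words.
#' @param models named list of `frequency_model`s (e.g. the three background
#'   corpora and the pooled combined model).
#' @return named numeric vector.
#' @export
frequency_feature_set <- function(words, models) {
  out <- numeric()
  for (nm in names(models)) {
    p <- rank_profile(words, models[[nm]], include_ov = FALSE)
    p_ov <- rank_profile(words, models[[nm]], include_ov = TRUE)
    f <- wff_features(p, prefix = nm)
    f[paste0(nm, "_mean_incl_ov")] <-
      if (length(p_ov$values) == 0L) NA_real_ else mean(p_ov$values)
    out <- c(out, f)
  }
  out
}

#' Serialize / load a frequency model as TSV
#'
#' The TSV carries `word<TAB>value` rows after two comment lines with the
#' corpus name and vocabulary size.
#'
#' @param model a `frequency_model`.
#' @param path output/input path.
#' @return `read_frequency_model` returns a `frequency_model`;
#'   `write_frequency_model` returns `path` invisibly.
#' @export
write_frequency_model <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# corpus_name=", model$corpus_name),
               paste0("# vocab_size=", model$vocab_size)), con)
  write.table(data.frame(word = names(model$rank_value),
                         value = unname(model$rank_value)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequency_model
#' @export
read_frequency_model <- function(path) {
  hdr <- readLines(path, n = 2L)
  name <- sub("^# corpus_name=", "", hdr[1])
  d <- read.delim(path, skip = 2L, stringsAsFactors = FALSE)
  structure(list(
    corpus_name = name,
    vocab_size = as.integer(sub("^# vocab_size=", "", hdr[2])),
    rank_value = setNames(as.numeric(d$value), as.character(d$word))
  ), class = "frequency_model")
}
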