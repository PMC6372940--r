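#' @title Per-document feature assembly
#' @description
#' Computes the full understandability feature vector of an HTML page under
#' one preprocessing setting: readability formulae and their raw components
#' (with per-word and per-sentence variants), medical-vocabulary features,
#' natural-language features, HTML tag counts (pipeline-independent, from
#' the raw HTML), and word-frequency rank features against any supplied
#' background models.
#' @name features
NULL

#' Full feature vector for one HTML document
#'
#' @param html raw HTML string.
#' @param doc_id document identifier.
#' @param pipeline,heuristic preprocessing setting (see
#'   [extract_document()]).
#' @param freq_models optional named list of [build_frequency_model()]
#'   results.
#' @param resources bundled lexical resources (see [rr_resources()]).
#' @return named numeric vector; readability scores are `NA` for documents
#'   with no extractable words.
#' @export
document_features <- function(html, doc_id = "doc",
                              pipeline = "boilerplate", heuristic = "FP",
                              freq_models = NULL,
                              resources = rr_resources()) {
  doc <- extract_document(html, doc_id, pipeline, heuristic)
  tok <- tokenize_text(doc$text, abbreviations = resources$abbreviations)
  sc <- surface_counts(tok, common_words = resources$common_words)
  w <- max(sc$words, 0L); s <- max(sc$sentences, 0L)
  rf <- if (w >= 1 && s >= 1) readability_scores(sc)
        else setNames(rep(NA_real_, 8L),
                      c("ari", "cli", "dci", "fkgl", "fre", "gfi", "lix", "smog"))
  comp <- unlist(sc)
  comp_norm <- normalize_features(comp, words = w, sentences = s)
  gmv <- affix_and_dictionary_counts(tok$words,
                                     prefixes = resources$prefixes,
                                     suffixes = resources$suffixes,
                                     acronyms = resources$acronyms,
                                     dictionaries = resources$dictionaries)
  chv_m <- match_concepts(tok, resources$chv)
  mesh_lex <- lexicon(resources$mesh$term, groups = resources$mesh$group,
                      name = "mesh")
  mesh_m <- match_concepts(tok, mesh_lex)
  nl <- c(pos_features(tok),
          sentiment_counts(tok$words, polarity = resources$polarity),
          lexical_membership_counts(tok$words,
                                    english_vocab = resources$english_vocab,
                                    stoplist = resources$stopwords))
  out <- c(rf, comp_norm,
           normalize_features(gmv, w, s),
           chv_features(chv_m),
           suppressMessages(mesh_features(mesh_m, resources$mesh)),
           normalize_features(nl, w, s),
           html_tag_features(html))
  if (!is.null(freq_models)) {
    out <- c(out, frequency_feature_set(tok$words, freq_models))
  }
  out
}

#' Feature matrix for a page collection
#'
#' @param pages named character vector of HTML strings (names are doc ids).
#' @inheritParams document_features
#' @return numeric matrix, one row per document.
#' @export
documents_feature_matrix <- function(pages, pipeline = "boilerplate",
                                     heuristic = "FP", freq_models = NULL,
                                     resources = rr_resources()) {
  stopifnot(!is.null(names(pages)))
  rows <- lapply(names(pages), function(id) {
    document_features(pages[[id]], id, pipeline, heuristic,
                      freq_models = freq_models, resources = resources)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(pages)
  m
}
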