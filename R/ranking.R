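#' @title Retrieval integration
#' @description
#' BM25 retrieval over a tokenized corpus, understandability-based reranking
#' of the top k results, reciprocal rank fusion of two runs, and five
#' learning-to-rank labeling strategies combining a relevance grade R with
#' an understandability score U, trained with a pairwise gradient-boosted
#' ranker. Runs use TREC conventions (`qid Q0 docid rank score tag`).
#' @name ranking
NULL

#' Construct a ranked run
#'
#' Normalizes a (qid, docid, score) table into a run: within each query,
#' documents are ordered by decreasing score with ties broken by docid, and
#' 1-based ranks assigned. Duplicate (qid, docid) pairs are an error.
#'
#' @param qid,docid character vectors.
#' @param score numeric scores.
#' @param tag run tag.
#' @return object of class `trec_run`: a data frame `qid`, `docid`, `rank`,
#'   `score` with a `tag` attribute.
#' @export
trec_run <- function(qid, docid, score, tag = "run") {
  d <- data.frame(qid = as.character(qid), docid = as.character(docid),
                  score = as.numeric(score), stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("qid", "docid")]))
    stop("duplicate (qid, docid) in run")
  d <- d[order(d$qid, -d$score, d$docid, method = "radix"), , drop = FALSE]
  d$rank <- if (nrow(d) == 0L) integer() else
    unlist(lapply(split(seq_len(nrow(d)), d$qid), seq_along),
           use.names = FALSE)
  # split() reorders groups by qid; rows are already qid-sorted so this aligns
  rownames(d) <- NULL
  structure(d[, c("qid", "docid", "rank", "score")], class = c("trec_run", "data.frame"),
            tag = tag)
}

run_tag <- function(run) attr(run, "tag", exact = TRUE)

#' Read / write runs in TREC format
#'
#' Six whitespace-separated columns: `qid Q0 docid rank score tag`.
#'
#' @param path file path.
#' @param run a `trec_run`.
#' @return `read_trec_run` returns a `trec_run`; `write_trec_run` returns
#'   `path` invisibly.
#' @export
read_trec_run <- function(path) {
  d <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("qid", "q0", "docid", "rank", "score", "tag"),
                  colClasses = c("character", "character", "character",
                                 "integer", "numeric", "character"))
  trec_run(d$qid, d$docid, d$score, tag = d$tag[1])
}

#' @rdname read_trec_run
#' @export
write_trec_run <- function(run, path) {
  stopifnot(inherits(run, "trec_run"))
  lines <- sprintf("%s Q0 %s %d %s %s", run$qid, run$docid, run$rank,
                   format(run$score, digits = 15, scientific = FALSE,
                          trim = TRUE),
                   run_tag(run))
  writeLines(lines, path)
  invisible(path)
}

#' Build an inverted index over a tokenized corpus
#'
#' @param docs named collection of documents (texts, word vectors or
#'   `tokenized_text`s); names are the doc ids.
#' @param doc_ids optional explicit doc ids.
#' @return object of class `rr_index` with term frequencies, document
#'   frequencies, lengths and averages.
#' @export
build_index <- function(docs, doc_ids = names(docs)) {
  tokens <- .rr_as_token_list(docs)
  if (is.null(doc_ids)) doc_ids <- paste0("d", seq_along(tokens))
  stopifnot(length(doc_ids) == length(tokens), !anyDuplicated(doc_ids))
  tf <- lapply(tokens, function(w) {
    if (length(w) == 0L) return(integer())
    tb <- table(w); setNames(as.integer(tb), names(tb))
  })
  names(tf) <- doc_ids
  doc_len <- vapply(tokens, length, integer(1))
  all_terms <- unlist(lapply(tf, names), use.names = FALSE)
  df <- table(all_terms)
  structure(list(
    tf = tf, df = setNames(as.integer(df), names(df)),
    doc_len = setNames(doc_len, doc_ids),
    avg_len = mean(doc_len), n_docs = length(tokens),
    total_len = sum(doc_len),
    cf = local({
      s <- unlist(tf, use.names = FALSE)
      tapply(s, all_terms, sum)
    })
  ), class = "rr_index")
}

#' BM25 scores for one query against every indexed document
#'
#' `score(d) = sum_t idf(t) * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len/avglen))`
#' with `idf(t) = ln((N - df + 0.5) / (df + 0.5) + 1)` (the +1-inside-log
#' variant, which never goes negative).
#'
#' @param index an `rr_index`.
#' @param query character vector of query words.
#' @param b,k1 BM25 parameters (defaults 0.75 and 1.2).
#' @return named numeric score vector over all documents.
#' @export
bm25_scores <- function(index, query, b = 0.75, k1 = 1.2) {
  stopifnot(inherits(index, "rr_index"))
  query <- tolower(query)
  scores <- setNames(numeric(index$n_docs), names(index$tf))
  if (length(query) == 0L) return(scores)
  n <- index$n_docs
  for (d in names(index$tf)) {
    tfd <- index$tf[[d]]
    len <- index$doc_len[[d]]
    s <- 0
    for (t in unique(query)) {
      tf <- tfd[t]
      if (is.na(tf)) next
      df <- index$df[[t]]
      idf <- log((n - df + 0.5) / (df + 0.5) + 1)
      s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / index$avg_len))
    }
    scores[d] <- s
  }
  scores
}

#' BM25 ranking for a set of queries
#'
#' @param queries named list of query word vectors (names are qids).
#' @param index an `rr_index` from [build_index()].
#' @param b,k1 BM25 parameters.
#' @param top_n keep at most this many documents per query (default all).
#' @param tag run tag.
#' @return a `trec_run`; queries with no words yield empty rankings.
#' @export
bm25_rank <- function(queries, index, b = 0.75, k1 = 1.2, top_n = Inf,
                      tag = "bm25") {
  rows <- lapply(names(queries), function(q) {
    if (length(queries[[q]]) == 0L) return(NULL)
    s <- bm25_scores(index, queries[[q]], b = b, k1 = k1)
    d <- data.frame(qid = q, docid = names(s), score = unname(s),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$score, d$docid, method = "radix"), , drop = FALSE]
    head(d, n = if (is.finite(top_n)) top_n else nrow(d))
  })
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) == 0L)
    return(trec_run(character(), character(), numeric(), tag = tag))
  trec_run(d$qid, d$docid, d$score, tag = tag)
}

#' Rerank the top k documents of a run by difficulty
#'
#' Within each query the set of top-k documents is preserved but reordered
#' by ascending difficulty (easiest first), with the original rank breaking
#' ties; ranks beyond k are unchanged. Documents without a difficulty score
#' are treated as hardest and sorted last within the top k. Set
#' `invert = TRUE` for estimators where higher output means easier.
#'
#' @param run a `trec_run`.
#' @param difficulty named numeric vector `docid -> difficulty estimate`.
#' @param k rank cut-off (the study used 15, 20 and 50); must be positive.
#' @param invert flip the difficulty direction.
#' @return a reranked `trec_run` (scores are replaced by `-new rank` so that
#'   score order matches the new ranking).
#' @export
rerank_topk <- function(run, difficulty, k, invert = FALSE) {
  stopifnot(inherits(run, "trec_run"))
  if (k <= 0) stop("k must be positive")
  pieces <- lapply(split(run, run$qid), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    kk <- min(k, nrow(d))
    if (kk > 1L) {
      top <- d[seq_len(kk), , drop = FALSE]
      diff <- unname(difficulty[top$docid])
      if (invert) diff <- -diff
      diff[is.na(diff)] <- Inf
      top <- top[order(diff, top$rank), , drop = FALSE]
      d[seq_len(kk), ] <- top
    }
    d$rank <- seq_len(nrow(d))
    d$score <- -as.numeric(d$rank)
    d
  })
  out <- do.call(rbind, pieces)
  structure_run <- trec_run(out$qid, out$docid, out$score,
                            tag = paste0(run_tag(run), "_rerank", k))
  structure_run
}

#' Reciprocal rank fusion of two runs
#'
#' `score(d) = sum over runs containing d of 1 / (c + rank(d))`, with the
#' conventional constant `c = 60`; fused lists are sorted by descending
#' score with docid tie-break. Symmetric in its two arguments up to
#' tie-breaking.
#'
#' @param run_a,run_b `trec_run`s over the same query set.
#' @param c rank-smoothing constant.
#' @param tag fused run tag.
#' @return a `trec_run`.
#' @export
rrf_fuse <- function(run_a, run_b, c = 60, tag = "rrf") {
  stopifnot(inherits(run_a, "trec_run"), inherits(run_b, "trec_run"))
  ab <- rbind(
    data.frame(qid = run_a$qid, docid = run_a$docid, rr = 1 / (c + run_a$rank)),
    data.frame(qid = run_b$qid, docid = run_b$docid, rr = 1 / (c + run_b$rank))
  )
  agg <- stats::aggregate(rr ~ qid + docid, data = ab, FUN = sum)
  trec_run(agg$qid, agg$docid, agg$rr, tag = tag)
}

#' Learning-to-rank labels from relevance and understandability
#'
#' The five strategies combine a relevance grade R with an understandability
#' score U. On the 5-point scale (`likert5`, U in 0..4, higher = easier by
#' default) the threshold is U >= 2; on the 0-100 scale (`range100`, 0 =
#' easiest) it is U <= 40:
#' \itemize{
#'   \item LTR1, LTR2: `F = R` (they differ only in feature set);
#'   \item LTR3: `F = R * U / 3` (likert5) or `F = R * (100 - U) / 100`
#'     (range100) — a proportional understandability penalty;
#'   \item LTR4: `F = R` when the document passes the threshold, else 0
#'     (train only on easy-to-read documents);
#'   \item LTR5: `F = 2 * R` when it passes, else `R` (boost easy-to-read
#'     documents).
#' }
#'
#' @param R numeric relevance grades.
#' @param U numeric understandability scores on the scale's range.
#' @param strategy `"LTR1"` .. `"LTR5"` (or integers 1..5).
#' @param scale `"likert5"` or `"range100"`.
#' @return numeric labels.
#' @export
ltr_label <- function(R, U, strategy, scale = c("likert5", "range100")) {
  scale <- match.arg(scale)
  if (is.numeric(strategy)) strategy <- paste0("LTR", strategy)
  strategy <- match.arg(strategy, paste0("LTR", 1:5))
  R <- as.numeric(R); U <- as.numeric(U)
  lim <- if (scale == "likert5") c(0, 4) else c(0, 100)
  if (any(U < lim[1] | U > lim[2], na.rm = TRUE))
    stop("understandability score outside the ", scale, " range")
  easy <- if (scale == "likert5") U >= 2 else U <= 40
  switch(strategy,
    LTR1 = ,
    LTR2 = R,
    LTR3 = if (scale == "likert5") R * U / 3 else R * (100 - U) / 100,
    LTR4 = ifelse(easy, R, 0),
    LTR5 = ifelse(easy, 2 * R, R)
  )
}

#' Feature set used by a strategy
#'
#' LTR1 uses retrieval (IR) features only; LTR2-LTR5 add the
#' understandability features.
#'
#' @param strategy `"LTR1"` .. `"LTR5"`.
#' @return `"ir_only"` or `"ir_plus_understandability"`.
#' @export
ltr_feature_set <- function(strategy) {
  if (is.numeric(strategy)) strategy <- paste0("LTR", strategy)
  strategy <- match.arg(strategy, paste0("LTR", 1:5))
  if (strategy == "LTR1") "ir_only" else "ir_plus_understandability"
}

#' Build title / body / whole-document field indexes for a page collection
#'
#' The title field holds the `<title>` text, the body field the text of the
#' naive extraction without the title, and the whole field their union —
#' the multifield layout conventional in learning-to-rank indexing.
#'
#' @param pages named character vector of HTML strings.
#' @return named list of three `rr_index` objects (`title`, `body`,
#'   `whole`).
#' @export
page_field_indexes <- function(pages) {
  stopifnot(!is.null(names(pages)))
  title <- list(); body <- list(); whole <- list()
  for (id in names(pages)) {
    blocks <- extract_blocks(pages[[id]], "naive")
    is_title <- blocks$kind == "title"
    t_tok <- tokenize_text(assemble_text(blocks[is_title, , drop = FALSE], "FP"))$words
    b_tok <- tokenize_text(assemble_text(blocks[!is_title, , drop = FALSE], "FP"))$words
    title[[id]] <- t_tok
    body[[id]] <- b_tok
    whole[[id]] <- c(t_tok, b_tok)
  }
  list(title = build_index(title), body = build_index(body),
       whole = build_index(whole))
}

#' Retrieval-model features over title/body/whole-document fields
#'
#' Generates 24 IR features per (query, document) pair: four weighting
#' models (BM25, TF-IDF, Dirichlet-smoothed language model, and query-term
#' coverage) over three fields (title, body, whole document), each raw and
#' divided by the field length (two length normalizations).
#'
#' @param queries named list of query word vectors.
#' @param fields named list of three `rr_index` objects: `title`, `body`,
#'   `whole` (see [build_index()]); all must index the same doc ids.
#' @param candidates optional data frame `qid`, `docid` restricting the
#'   pairs; defaults to every (query, doc) pair.
#' @return data frame `qid`, `docid` plus 24 feature columns.
#' @export
ir_features <- function(queries, fields, candidates = NULL) {
  stopifnot(all(c("title", "body", "whole") %in% names(fields)))
  ids <- names(fields$whole$tf)
  if (is.null(candidates)) {
    candidates <- expand.grid(qid = names(queries), docid = ids,
                              stringsAsFactors = FALSE)
  }
  candidates <- candidates[order(candidates$qid, candidates$docid,
                                 method = "radix"), c("qid", "docid")]
  rownames(candidates) <- NULL
  out <- candidates
  mu <- 100  # Dirichlet smoothing mass
  for (fn in c("title", "body", "whole")) {
    idx <- fields[[fn]]
    for (q in unique(candidates$qid)) {
      sel <- candidates$qid == q
      docs <- candidates$docid[sel]
      query <- tolower(queries[[q]])
      bm <- bm25_scores(idx, query)[docs]
      len <- pmax(idx$doc_len[docs], 1L)
      tfidf <- setNames(numeric(length(docs)), docs)
      qlm <- setNames(numeric(length(docs)), docs)
      cov <- setNames(numeric(length(docs)), docs)
      for (t in unique(query)) {
        df <- idx$df[t]
        cf <- idx$cf[t]
        if (is.na(df)) next
        idf <- log(idx$n_docs / df) + 1
        tfv <- vapply(docs, function(d) {
          v <- idx$tf[[d]][t]; if (is.na(v)) 0 else as.numeric(v)
        }, numeric(1))
        tfidf <- tfidf + tfv * idf
        p_c <- cf / max(idx$total_len, 1L)
        qlm <- qlm + log((tfv + mu * p_c) / (idx$doc_len[docs] + mu))
        cov <- cov + as.numeric(tfv > 0)
      }
      block <- cbind(bm25 = unname(bm), tfidf = unname(tfidf),
                     dirichlet = unname(qlm), coverage = unname(cov))
      for (m in colnames(block)) {
        out[sel, paste(m, fn, "raw", sep = "_")] <- block[, m]
        out[sel, paste(m, fn, "norm", sep = "_")] <- block[, m] / unname(len)
      }
    }
  }
  out
}

#' Train a pairwise gradient-boosted ranker
#'
#' Fits a tree-boosted pairwise learning-to-rank model on per-query
#' candidate features with labels from [ltr_label()]. Training is
#' reproducible for a fixed seed (single-threaded boosting).
#'
#' @param features data frame with `qid`, `docid` and numeric feature
#'   columns (missing values allowed; trees route them natively).
#' @param labels numeric label vector aligned with `features` rows; must
#'   contain at least two distinct values.
#' @param seed integer seed.
#' @param nrounds boosting rounds (default 100).
#' @return object of class `ltr_ranker` recording the feature schema.
#' @export
train_ltr <- function(features, labels, seed = 1L, nrounds = 100) {
  stopifnot(all(c("qid", "docid") %in% names(features)))
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: need at least two distinct label values")
  ord <- order(features$qid, method = "radix")
  features <- features[ord, , drop = FALSE]
  labels <- labels[ord]
  fcols <- setdiff(names(features), c("qid", "docid"))
  x <- as.matrix(features[, fcols, drop = FALSE])
  group <- as.integer(table(factor(features$qid, levels = unique(features$qid))))
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = labels, group = group)
  fit <- xgboost::xgb.train(
    params = list(objective = "rank:pairwise", eta = 0.1, max_depth = 4,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0)
  structure(list(fit = fit, feature_names = fcols, seed = seed),
            class = "ltr_ranker")
}

#' Apply a trained ranker to candidates
#'
#' @param ranker an `ltr_ranker`.
#' @param features data frame `qid`, `docid` + the training feature columns
#'   (schema mismatch is an error).
#' @param tag run tag.
#' @return a `trec_run` ordered by descending model score per query, docid
#'   tie-break.
#' @export
apply_ltr <- function(ranker, features, tag = "ltr") {
  stopifnot(inherits(ranker, "ltr_ranker"))
  if (!all(ranker$feature_names %in% names(features)))
    stop("feature schema mismatch between training and application")
  if (nrow(features) == 0L)
    return(trec_run(character(), character(), numeric(), tag = tag))
  x <- as.matrix(features[, ranker$feature_names, drop = FALSE])
  scores <- predict(ranker$fit, xgboost::xgb.DMatrix(x))
  trec_run(features$qid, features$docid, scores, tag = tag)
}
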