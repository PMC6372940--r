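#' @title Seeded synthetic fixtures
#' @description
#' Deterministic generators for every input the toolkit consumes: three
#' background corpora whose documents differ systematically in sentence
#' length, lexicon difficulty and emotional-word density (standing in for a
#' lay health forum, encyclopedic articles and biomedical literature); HTML
#' pages with headings, lists, tables, paragraphs, a boilerplate navigation
#' bar and a planted difficulty tier; and queries with graded relevance,
#' understandability judgments on either assessment scale, and a BM25
#' baseline run with a deliberate fraction of retrieved-but-unjudged
#' documents. Identical configuration and seed give byte-identical output.
#' @name synthetic_fixtures
NULL

#' Generator configuration
#'
#' Defaults define the package's reference study conditions: three corpora
#' of 60 documents each; mean sentence lengths 8 / 14 / 22 words and
#' emotional-word densities 0.10 / 0.04 / 0.01 for tiers 1-3; 40 pages; 10
#' queries with 12 judged documents each on the 0-100 scale; and a
#' relevance-understandability correlation of -0.4 (relevant documents tend
#' to be harder to read, as observed in consumer health search).
#'
#' @param seed integer master seed.
#' @param docs_per_corpus documents per background corpus.
#' @param vocab_sizes vocabulary sizes for the easy/medium/hard tiers.
#' @param sentence_len mean sentence length (words) per tier.
#' @param emotional_density probability that a token is an emotional word,
#'   per tier.
#' @param page_count number of HTML pages.
#' @param query_count number of queries.
#' @param judged_per_query judged documents per query.
#' @param scale judgment scale: `"range100"` or `"likert5"`.
#' @param rel_und_correlation target correlation in `[-1, 1]` between the
#'   relevance grade and understandability (easiness); negative means
#'   relevant documents tend to be hard.
#' @param punct_missing probability that a structural block (heading, list
#'   item, cell, title) lacks terminal punctuation.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 42L, docs_per_corpus = 60L,
                             vocab_sizes = c(150L, 150L, 200L),
                             sentence_len = c(8, 14, 22),
                             emotional_density = c(0.10, 0.04, 0.01),
                             page_count = 40L, query_count = 10L,
                             judged_per_query = 12L,
                             scale = c("range100", "likert5"),
                             rel_und_correlation = -0.4,
                             punct_missing = 0.7) {
  stopifnot(docs_per_corpus > 0, page_count > 0, query_count > 0,
            judged_per_query > 0,
            rel_und_correlation >= -1, rel_und_correlation <= 1,
            length(sentence_len) == 3, length(emotional_density) == 3)
  structure(list(seed = as.integer(seed), docs_per_corpus = docs_per_corpus,
                 vocab_sizes = vocab_sizes, sentence_len = sentence_len,
                 emotional_density = emotional_density,
                 page_count = page_count, query_count = query_count,
                 judged_per_query = judged_per_query,
                 scale = match.arg(scale),
                 rel_und_correlation = rel_und_correlation,
                 punct_missing = punct_missing),
            class = "generator_config")
}

# deterministic tier word stocks; hard-tier words are synthesized from
# Greco-Latin morphemes so their length/syllable difficulty is controllable
.rr_word_stocks <- function(cfg) {
  res <- rr_resources()
  easy <- res$common_words[nchar(res$common_words) >= 2]
  medium <- sort(unique(c(
    read_wordlist(rr_extdata("english_extra.txt")),
    res$dictionaries$icd[1:25], res$dictionaries$medspell[1:25]
  )))
  pre <- c("hyper", "hypo", "cardio", "neuro", "gastro", "hemato", "broncho",
           "dermato", "osteo", "nephro", "immuno", "thrombo")
  mid <- c("vascul", "pulmon", "glycer", "angi", "myel", "cyt", "lymph",
           "fibr", "sclerot", "metabol")
  suf <- c("itis", "osis", "emia", "opathy", "ectomy", "ization", "ogenesis",
           "ometry")
  hard <- as.vector(outer(as.vector(outer(pre, mid, paste0)), suf, paste0))
  list(easy = utils::head(easy, cfg$vocab_sizes[1]),
       medium = utils::head(medium, cfg$vocab_sizes[2]),
       hard = utils::head(hard, cfg$vocab_sizes[3]),
       emotional = names(res$polarity)[res$polarity != "neu"])
}

# mixture weights over (easy, medium, hard) stocks per tier; tiers overlap
# so downstream classification is non-trivial
.rr_tier_mix <- rbind(c(0.88, 0.10, 0.02),
                      c(0.40, 0.45, 0.15),
                      c(0.15, 0.25, 0.60))

.rr_gen_sentence <- function(tier, stocks, cfg) {
  n <- max(3L, rpois(1, cfg$sentence_len[tier]))
  pick <- sample.int(3L, n, replace = TRUE, prob = .rr_tier_mix[tier, ])
  words <- vapply(pick, function(s) {
    st <- stocks[[s]]
    st[sample.int(length(st), 1L)]
  }, character(1))
  emo <- runif(n) < cfg$emotional_density[tier]
  if (any(emo)) {
    words[emo] <- stocks$emotional[sample.int(length(stocks$emotional),
                                              sum(emo), replace = TRUE)]
  }
  words
}

.rr_gen_doc_text <- function(tier, stocks, cfg, n_sentences = NULL) {
  if (is.null(n_sentences)) n_sentences <- sample(4:9, 1L)
  sents <- vapply(seq_len(n_sentences), function(i) {
    w <- .rr_gen_sentence(tier, stocks, cfg)
    paste0(paste(w, collapse = " "), ".")
  }, character(1))
  paste(sents, collapse = " ")
}

#' Generate the three labeled background corpora
#'
#' Label 1 documents use short sentences over the easy vocabulary with high
#' emotional-word density; label 3 documents use long sentences over a
#' synthesized polysyllabic vocabulary; label 2 is intermediate. The tier
#' vocabularies overlap, so separating the classes is non-trivial.
#'
#' @param cfg a [generator_config()].
#' @return list with `texts` (character vector), `labels` (integer 1/2/3).
#' @export
gen_background_corpora <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  stocks <- .rr_word_stocks(cfg)
  texts <- character(0); labels <- integer(0)
  for (tier in 1:3) {
    texts <- c(texts, vapply(seq_len(cfg$docs_per_corpus), function(i) {
      .rr_gen_doc_text(tier, stocks, cfg)
    }, character(1)))
    labels <- c(labels, rep(tier, cfg$docs_per_corpus))
  }
  list(texts = texts, labels = labels)
}

.rr_maybe_strip_punct <- function(text, cfg) {
  if (runif(1) < cfg$punct_missing) sub("\\.$", "", text) else text
}

#' Generate HTML pages with planted structure and difficulty
#'
#' Each page carries a title, a 40-link navigation bar (ground-truth
#' boilerplate), headings, paragraphs, a content list, and a table; text is
#' drawn from the page's difficulty tier (1 = easy ... 3 = hard, assigned
#' round-robin). Structural blocks lack terminal punctuation with
#' probability `cfg$punct_missing`. The manifest records every planted
#' property; `blocks` holds per-page ground truth block labels.
#'
#' @param cfg a [generator_config()].
#' @return list with `pages` (named character vector of HTML), `manifest`
#'   (data frame) and `blocks` (list of per-page data frames `text`, `kind`,
#'   `boilerplate`).
#' @export
gen_html_pages <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed + 1L)
  stocks <- .rr_word_stocks(cfg)
  pages <- character(cfg$page_count)
  ids <- sprintf("page%03d", seq_len(cfg$page_count))
  manifest <- vector("list", cfg$page_count)
  blocks <- vector("list", cfg$page_count)
  nav_words <- c("home", "about", "contact", "news", "topics", "search",
                 "help", "login", "register", "sitemap")
  for (i in seq_len(cfg$page_count)) {
    tier <- ((i - 1L) %% 3L) + 1L
    n_head <- sample(2:4, 1L)
    n_para <- sample(2:4, 1L)
    n_items <- sample(3:5, 1L)
    n_cells <- 4L
    n_nav <- 40L
    title <- .rr_maybe_strip_punct(
      paste0(paste(.rr_gen_sentence(tier, stocks, cfg)[1:4], collapse = " "), "."),
      cfg)
    nav_texts <- sample(nav_words, n_nav, replace = TRUE)
    nav_links <- sprintf('<li><a href="#%d">%s</a></li>', seq_len(n_nav),
                         nav_texts)
    headings <- vapply(seq_len(n_head), function(h) .rr_maybe_strip_punct(
      paste0(paste(.rr_gen_sentence(tier, stocks, cfg)[1:5], collapse = " "), "."),
      cfg), character(1))
    paras <- vapply(seq_len(n_para), function(p)
      .rr_gen_doc_text(tier, stocks, cfg, n_sentences = sample(2:4, 1L)),
      character(1))
    items <- vapply(seq_len(n_items), function(it) .rr_maybe_strip_punct(
      paste0(paste(.rr_gen_sentence(tier, stocks, cfg)[1:7], collapse = " "), "."),
      cfg), character(1))
    cells <- vapply(seq_len(n_cells), function(cl) .rr_maybe_strip_punct(
      paste0(paste(.rr_gen_sentence(tier, stocks, cfg)[1:6], collapse = " "), "."),
      cfg), character(1))
    body <- c(
      sprintf('<ul class="nav">%s</ul>', paste(nav_links, collapse = "")),
      sprintf("<h%d>%s</h%d>", pmin(seq_len(n_head), 3L), headings,
              pmin(seq_len(n_head), 3L)),
      sprintf("<p>%s</p>", paras),
      sprintf("<ul>%s</ul>", paste(sprintf("<li>%s</li>", items), collapse = "")),
      sprintf("<table><tr>%s</tr><tr>%s</tr></table>",
              paste(sprintf("<td>%s</td>", cells[1:2]), collapse = ""),
              paste(sprintf("<td>%s</td>", cells[3:4]), collapse = ""))
    )
    pages[i] <- sprintf(
      "<html><head><title>%s</title></head><body>%s</body></html>",
      title, paste(body, collapse = ""))
    manifest[[i]] <- data.frame(
      doc_id = ids[i], tier = tier, n_headings = n_head,
      n_paragraphs = n_para, n_content_list_items = n_items,
      n_table_cells = n_cells, n_nav_links = n_nav,
      stringsAsFactors = FALSE)
    blocks[[i]] <- data.frame(
      text = c(title, nav_texts, headings, paras, items, cells),
      kind = c("title", rep("list_item", n_nav), rep("heading", n_head),
               rep("paragraph", n_para), rep("list_item", n_items),
               rep("table_cell", n_cells)),
      boilerplate = c(FALSE, rep(TRUE, n_nav),
                      rep(FALSE, n_head + n_para + n_items + n_cells)),
      stringsAsFactors = FALSE)
  }
  names(pages) <- ids
  list(pages = pages, manifest = do.call(rbind, manifest),
       blocks = setNames(blocks, ids))
}

#' Generate queries, graded judgments and a baseline run
#'
#' Queries sample informative words from a target page. The baseline run is
#' BM25 over the generated pages (top 20 per query); the top
#' `judged_per_query` documents of each query are judged, deliberately
#' leaving deeper retrieved documents unassessed so that residuals and
#' condensed measures are exercised. Relevance grades (0/1/2) mix a
#' topicality component (the BM25 signal) with an easiness component whose
#' weight is calibrated so that the correlation between grade and easiness
#' approximates `cfg$rel_und_correlation`. Understandability scores follow
#' the page's planted difficulty tier: on the 0-100 scale (0 = easiest)
#' they are drawn from a bimodal distribution, mimicking slider assessments
#' anchored at an "average" midpoint.
#'
#' @param cfg a [generator_config()].
#' @param pages a [gen_html_pages()] result (generated from `cfg` when
#'   omitted).
#' @return list with `queries` (named list of word vectors), `judgments`
#'   (an `rr_judgments` data frame), `run` (baseline `trec_run`) and
#'   `pages`.
#' @export
gen_topics_judgments_runs <- function(cfg = generator_config(), pages = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(pages)) pages <- gen_html_pages(cfg)
  set.seed(cfg$seed + 2L)
  docs <- vapply(names(pages$pages), function(id)
    extract_document(pages$pages[[id]], id, "boilerplate", "FP")$text,
    character(1))
  index <- build_index(as.list(docs), doc_ids = names(docs))
  stopw <- rr_resources()$stopwords
  queries <- lapply(seq_len(cfg$query_count), function(q) {
    target <- ((q - 1L) %% cfg$page_count) + 1L
    w <- tokenize_text(docs[[target]])$words
    w <- unique(w[nchar(w) >= 4 & !(w %in% stopw)])
    if (length(w) < 2L) w <- unique(tokenize_text(docs[[target]])$words)
    w[sample.int(length(w), min(3L, length(w)))]
  })
  names(queries) <- sprintf("q%02d", seq_len(cfg$query_count))
  run <- bm25_rank(queries, index, top_n = 20L, tag = "bm25_baseline")

  tier_of <- setNames(pages$manifest$tier, pages$manifest$doc_id)
  rho <- cfg$rel_und_correlation
  rho_lat <- max(-0.98, min(0.98, rho / 0.85))  # grade-cut attenuation
  a_top <- sqrt(max(0, 1 - rho_lat^2)) * 0.7    # topicality weight
  jrows <- lapply(names(queries), function(q) {
    rq <- run[run$qid == q, , drop = FALSE]
    rq <- rq[order(rq$rank), , drop = FALSE]
    judged <- utils::head(rq, cfg$judged_per_query)
    m <- nrow(judged)
    tz <- as.numeric(scale(judged$score))
    if (any(!is.finite(tz))) tz <- rep(0, m)
    dz <- (tier_of[judged$docid] - 2 + rnorm(m, 0, 0.6)) / sqrt(2 / 3 + 0.36)
    ez <- -dz
    noise_sd <- sqrt(max(0.02, 1 - rho_lat^2 - a_top^2))
    rz <- a_top * tz + rho_lat * ez + rnorm(m, 0, noise_sd)
    rel <- findInterval(rz, c(qnorm(0.55), qnorm(0.85)))
    und <- if (cfg$scale == "range100") {
      round(100 * pbeta(stats::pnorm(1.4 * dz), 0.5, 0.5))
    } else {
      pmin(4L, pmax(0L, findInterval(stats::pnorm(ez),
                                     c(0.2, 0.4, 0.6, 0.8))))
    }
    data.frame(qid = q, docid = judged$docid, rel = rel, und = und,
               stringsAsFactors = FALSE)
  })
  j <- do.call(rbind, jrows)
  list(queries = queries,
       judgments = judgments(j$qid, j$docid, j$rel, j$und, scale = cfg$scale),
       run = run, pages = pages)
}
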