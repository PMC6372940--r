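# shared fixture builders; everything is generated in code, seeded

# random tag soup for extraction property tests (independent of the
# package's own page generator)
random_tag_soup <- function(seed) {
  set.seed(seed)
  tags <- c("p", "h1", "h2", "li", "td", "div", "span", "b")
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta", "health", "advice", "doctor", "symptom")
  n <- sample(3:10, 1)
  parts <- vapply(seq_len(n), function(i) {
    tg <- sample(tags, 1)
    txt <- paste(sample(words, sample(2:8, 1), replace = TRUE), collapse = " ")
    if (runif(1) < 0.5) txt <- paste0(txt, sample(c(".", "!", "?"), 1))
    closing <- runif(1) < 0.9  # sometimes leave tags unclosed (malformed)
    if (closing) sprintf("<%s>%s</%s>", tg, txt, tg)
    else sprintf("<%s>%s", tg, txt)
  }, character(1))
  paste(parts, collapse = "")
}

sentence_count <- function(text) length(tokenize_text(text)$sentences)

# small judged run: m docs, gains supplied in rank order
toy_run <- function(qid = "q1", n = 10, tag = "toy") {
  trec_run(rep(qid, n), sprintf("d%02d", seq_len(n)),
           score = rev(seq_len(n)), tag = tag)
}

# judgments for toy_run: rel/und vectors aligned with rank order;
# NA entries mean "leave this document unassessed"
toy_judgments <- function(run, rel, und, scale = "range100") {
  keep <- !is.na(rel)
  judgments(run$qid[keep], run$docid[keep], rel[keep], und[keep],
            scale = scale)
}

# independent direct-sum RBP oracle: gains in rank order, NA = unassessed
rbp_oracle <- function(gains, p, n) {
  value <- 0; residual <- 0
  for (k in seq_len(n)) {
    w <- (1 - p) * p^(k - 1)
    g <- if (k <= length(gains)) gains[k] else NA_real_
    if (is.na(g)) residual <- residual + w else value <- value + w * g
  }
  c(value = value, residual = residual + p^n)
}
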