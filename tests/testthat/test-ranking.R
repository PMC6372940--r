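test_that("runs normalize ordering, ranks and round-trip TREC format", {
  r <- trec_run(c("q1", "q1", "q2"), c("b", "a", "a"), c(1, 2, 3), tag = "t")
  expect_equal(r$docid[r$qid == "q1"], c("a", "b"))
  expect_equal(r$rank, c(1L, 2L, 1L))
  expect_error(trec_run(c("q1", "q1"), c("a", "a"), c(1, 2)), "duplicate")
  # score ties break by docid
  r2 <- trec_run(rep("q", 3), c("c", "a", "b"), c(1, 1, 1))
  expect_equal(r2$docid, c("a", "b", "c"))
  path <- tempfile(fileext = ".run")
  write_trec_run(r, path)
  r3 <- read_trec_run(path)
  expect_equal(r3$qid, r$qid)
  expect_equal(r3$docid, r$docid)
  expect_equal(r3$rank, r$rank)
  expect_equal(r3$score, r$score)
  # writing the re-read run reproduces the file exactly
  path2 <- tempfile(fileext = ".run")
  write_trec_run(r3, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("BM25 matches a hand-evaluated formula oracle on a toy corpus", {
  docs <- list(d1 = c("heart", "attack", "symptoms"),
               d2 = c("heart", "heart", "rate"),
               d3 = c("broken", "bone"))
  idx <- build_index(docs)
  b <- 0.75; k1 <- 1.2
  oracle <- function(q, doc_words) {
    len <- length(doc_words); avg <- mean(lengths(docs)); n <- 3
    s <- 0
    for (t in unique(q)) {
      tf <- sum(doc_words == t)
      if (tf == 0) next
      df <- sum(vapply(docs, function(d) t %in% d, logical(1)))
      idf <- log((n - df + 0.5) / (df + 0.5) + 1)
      s <- s + idf * tf * (k1 + 1) / (tf + k1 * (1 - b + b * len / avg))
    }
    s
  }
  q <- c("heart", "attack")
  got <- bm25_scores(idx, q)
  for (d in names(docs)) {
    expect_equal(unname(got[d]), oracle(q, docs[[d]]), tolerance = 1e-9)
  }
  # a term absent everywhere scores 0 for every document
  expect_true(all(bm25_scores(idx, "absent") == 0))
  # only one document contains the term: it ranks first
  run <- bm25_rank(list(q1 = "bone"), idx)
  expect_equal(run$docid[run$rank == 1], "d3")
  # empty query gives an empty ranking
  expect_equal(nrow(bm25_rank(list(q1 = character()), idx)), 0L)
})

test_that("top-k reranking reorders by difficulty and preserves the rest", {
  run <- toy_run(n = 5)
  expect_error(rerank_topk(run, c(d01 = 1), k = 0), "positive")
  # k = 1 leaves the run unchanged
  r1 <- rerank_topk(run, setNames(runif(5), run$docid), k = 1)
  expect_equal(r1$docid, run$docid)
  # equal difficulties keep the original stable order
  r2 <- rerank_topk(run, setNames(rep(1, 5), run$docid), k = 3)
  expect_equal(r2$docid, run$docid)
  # difficulties (5, 2, 9) on the top 3 give order (2nd, 1st, 3rd)
  diff <- setNames(c(5, 2, 9), run$docid[1:3])
  r3 <- rerank_topk(run, diff, k = 3)
  expect_equal(r3$docid[1:3], run$docid[c(2, 1, 3)])
  expect_equal(r3$docid[4:5], run$docid[4:5])
  # missing difficulty sorts last within the top k
  diff2 <- setNames(c(5, 2), run$docid[1:2])
  r4 <- rerank_topk(run, diff2, k = 3)
  expect_equal(r4$docid[3], run$docid[3])
  # invert flag flips the direction
  r5 <- rerank_topk(run, diff, k = 3, invert = TRUE)
  expect_equal(r5$docid[1:3], run$docid[c(3, 1, 2)])
})

test_that("reranking never changes the top-k set nor deeper ranks", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:25, 1)
    run <- trec_run(rep("q", n), sprintf("d%03d", sample(500, n)),
                    score = runif(n))
    k <- sample(c(3, 10, 15), 1)
    diffic <- setNames(runif(n), run$docid)
    if (seed %% 3 == 0) diffic <- diffic[-(1:2)]  # some missing scores
    rr <- rerank_topk(run, diffic, k = k)
    kk <- min(k, n)
    expect_setequal(rr$docid[seq_len(kk)], run$docid[seq_len(kk)])
    if (kk < n) {
      expect_equal(rr$docid[(kk + 1):n], run$docid[(kk + 1):n])
    }
  }
})

test_that("reciprocal rank fusion follows the 1/(c + rank) formula", {
  run <- toy_run(n = 4)
  fused <- rrf_fuse(run, run)
  expect_equal(fused$docid, run$docid)          # self-fusion keeps the order
  expect_equal(fused$score[1], 2 / (60 + 1))    # rank 1 in both runs
  # hand-computed oracle on two 3-doc runs
  a <- trec_run(rep("q", 3), c("x", "y", "z"), c(3, 2, 1))
  b <- trec_run(rep("q", 3), c("z", "x", "y"), c(3, 2, 1))
  f <- rrf_fuse(a, b, c = 60)
  oracle <- sort(c(x = 1/61 + 1/62, y = 1/62 + 1/63, z = 1/63 + 1/61),
                 decreasing = TRUE)
  expect_equal(setNames(f$score, f$docid), oracle)
  # symmetry up to tie-breaking
  f2 <- rrf_fuse(b, a, c = 60)
  expect_equal(f$docid, f2$docid)
  expect_equal(f$score, f2$score)
})

test_that("learning-to-rank labels reproduce the five strategies", {
  expect_equal(ltr_label(2, 50, "LTR3", "range100"), 1.0)
  expect_equal(ltr_label(1, 41, "LTR4", "range100"), 0)
  expect_equal(ltr_label(1, 40, "LTR5", "range100"), 2)
  expect_equal(ltr_label(2, 3, "LTR3", "likert5"), 2)
  expect_equal(ltr_label(1, 1, "LTR4", "likert5"), 0)
  expect_equal(ltr_label(1, 2, "LTR5", "likert5"), 2)
  expect_equal(ltr_label(2, 90, "LTR1", "range100"), 2)
  expect_error(ltr_label(1, 150, "LTR3", "range100"), "outside")
  expect_error(ltr_label(1, 5, "LTR3", "likert5"), "outside")
  expect_equal(ltr_feature_set("LTR1"), "ir_only")
  expect_equal(ltr_feature_set("LTR5"), "ir_plus_understandability")
})

test_that("the field indexes expose 24 retrieval features", {
  pages <- gen_html_pages(generator_config(seed = 8, page_count = 6))
  fields <- page_field_indexes(pages$pages)
  q <- list(q1 = c("health", "advice"), q2 = c("doctor"))
  f <- ir_features(q, fields)
  expect_equal(ncol(f) - 2L, 24L)
  expect_equal(nrow(f), 2L * 6L)
  expect_true(all(is.finite(as.matrix(f[, -(1:2)]))))
})

test_that("the pairwise ranker learns a feature that defines the labels", {
  set.seed(10)
  n_q <- 12; n_d <- 8
  feats <- expand.grid(qid = sprintf("q%02d", 1:n_q),
                       docid = sprintf("d%02d", 1:n_d),
                       stringsAsFactors = FALSE)
  feats$feature_x <- runif(nrow(feats))
  feats$noise <- runif(nrow(feats))
  labels <- feats$feature_x           # label IS feature x
  train_q <- sprintf("q%02d", 1:8)
  rk <- train_ltr(feats[feats$qid %in% train_q, ],
                  labels[feats$qid %in% train_q], seed = 1)
  hold <- feats[!(feats$qid %in% train_q), ]
  run <- apply_ltr(rk, hold)
  # per held-out query, the model ordering tracks feature_x
  for (q in unique(hold$qid)) {
    got <- run$docid[run$qid == q]
    want <- hold$docid[hold$qid == q][order(-hold$feature_x[hold$qid == q])]
    expect_gte(cor(match(got, want), seq_along(want), method = "spearman"),
               0.85)
  }
  # same seed twice gives identical rankings
  rk2 <- train_ltr(feats[feats$qid %in% train_q, ],
                   labels[feats$qid %in% train_q], seed = 1)
  run2 <- apply_ltr(rk2, hold)
  expect_identical(run$docid, run2$docid)
  expect_error(train_ltr(feats, rep(1, nrow(feats))), "degenerate")
  # single candidate ranks first; empty candidates give an empty run
  one <- apply_ltr(rk, feats[1, ])
  expect_equal(one$rank, 1L)
  expect_equal(nrow(apply_ltr(rk, feats[0, ])), 0L)
  expect_error(apply_ltr(rk, data.frame(qid = "q", docid = "d")), "schema")
})
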