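#' @title Understandability-aware retrieval evaluation
#' @description
#' Rank-biased precision (RBP) with residuals; the understandability-biased
#' uRBP, whose per-rank gain is the product of a binary relevance gain and a
#' binary understandability gain; separate RBP_r and RBP_u with their
#' harmonic-mean combination MM_RBP; condensed variants computed after
#' deleting unassessed documents; the count of unassessed documents in the
#' top n (Unj@n); correlation coefficients between estimator output and
#' human assessments; and a paired randomization test for per-query score
#' differences.
#' @name evaluation
NULL

#' Evaluation configuration
#'
#' @param p RBP persistence (default 0.8, `0 < p < 1`).
#' @param n evaluation depth (default 10, matching shallow pools).
#' @param U understandability gain threshold on the 0-100 scale (default
#'   40; a document is understandable when its score is `<= U`, the
#'   boundary-inclusive reading that matches the labeling threshold).
#' @param scale `"range100"` (0 = easiest) or `"likert5"` (0-4).
#' @param likert_direction for `likert5`: `"high_easy"` (default; gain when
#'   `U >= 3`, i.e. easy or somewhat easy) or `"low_easy"` (gain when
#'   `U <= 1`).
#' @return a list of class `eval_config`.
#' @export
eval_config <- function(p = 0.8, n = 10, U = 40,
                        scale = c("range100", "likert5"),
                        likert_direction = c("high_easy", "low_easy")) {
  stopifnot(p > 0, p < 1, n >= 1)
  structure(list(p = p, n = as.integer(n), U = U,
                 scale = match.arg(scale),
                 likert_direction = match.arg(likert_direction)),
            class = "eval_config")
}

#' Assemble judgments from qrels and understandability assessments
#'
#' @param qid,docid identifiers.
#' @param rel graded relevance (0 = not relevant; grades >= 1 count as
#'   relevant).
#' @param und understandability score on the configured scale.
#' @param scale `"range100"` or `"likert5"`.
#' @return data frame of class `rr_judgments`; at most one row per
#'   (qid, docid).
#' @export
judgments <- function(qid, docid, rel, und, scale = "range100") {
  d <- data.frame(qid = as.character(qid), docid = as.character(docid),
                  rel = as.numeric(rel), und = as.numeric(und),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d[c("qid", "docid")]))
    stop("duplicate (qid, docid) judgment")
  structure(d, class = c("rr_judgments", "data.frame"), scale = scale)
}

#' Read TREC qrels (`qid 0 docid rel`) and an understandability file
#' (`qid 0 docid score`), merging them into judgments
#'
#' Pairs present in only one of the two files are dropped with a message.
#'
#' @param qrels_path,und_path file paths.
#' @param scale understandability scale of the second file.
#' @return an `rr_judgments` data frame.
#' @export
read_judgments <- function(qrels_path, und_path, scale = "range100") {
  q <- read.table(qrels_path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("qid", "z", "docid", "rel"))
  u <- read.table(und_path, header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("qid", "z", "docid", "und"))
  m <- merge(q[c("qid", "docid", "rel")], u[c("qid", "docid", "und")],
             by = c("qid", "docid"))
  dropped <- nrow(q) + nrow(u) - 2 * nrow(m)
  if (dropped > 0) message("read_judgments: ", dropped,
                           " unmatched judgment line(s) dropped")
  judgments(m$qid, m$docid, m$rel, m$und, scale = scale)
}

#' Binary relevance gain
#'
#' 1 iff the graded relevance is at least "somewhat relevant" (grade >= 1).
#'
#' @param rel numeric relevance grades.
#' @return 0/1 vector.
#' @export
rel_gain <- function(rel) as.numeric(rel >= 1)

#' Binary understandability gain
#'
#' On the 0-100 scale (0 = easiest): gain 1 iff `score <= cfg$U`. On the
#' 5-point scale: gain 1 iff the label falls in the two easiest levels
#' (`>= 3` under the default high-is-easy direction, `<= 1` otherwise).
#'
#' @param und numeric understandability scores.
#' @param cfg an [eval_config()].
#' @return 0/1 vector.
#' @export
und_gain <- function(und, cfg = eval_config()) {
  if (cfg$scale == "range100") as.numeric(und <= cfg$U)
  else if (cfg$likert_direction == "high_easy") as.numeric(und >= 3)
  else as.numeric(und <= 1)
}

# core RBP machinery: gains is a numeric vector in rank order with NA for
# unassessed documents; ranks beyond the run length count as unassessed.
.rr_rbp <- function(gains, p, n) {
  k <- seq_len(n)
  g <- rep(NA_real_, n)
  take <- seq_len(min(n, length(gains)))
  g[take] <- gains[take]
  w <- (1 - p) * p^(k - 1)
  value <- sum(w * ifelse(is.na(g), 0, g))
  residual <- sum(w[is.na(g)]) + p^n
  c(value = value, residual = residual)
}

.rr_gain_vectors <- function(run_q, judg, cfg) {
  key <- paste(judg$qid, judg$docid)
  idx <- match(paste(run_q$qid, run_q$docid), key)
  r <- ifelse(is.na(idx), NA_real_, rel_gain(judg$rel[idx]))
  u <- ifelse(is.na(idx), NA_real_, und_gain(judg$und[idx], cfg))
  list(r = r, u = u, assessed = !is.na(idx))
}

#' Harmonic-mean combination of relevance and understandability RBP
#'
#' `MM_RBP = 2 * r * u / (r + u)`, defined as 0 when both inputs are 0.
#'
#' @param rbp_r,rbp_u values in `[0, 1]`.
#' @return the harmonic mean.
#' @export
mm_rbp <- function(rbp_r, rbp_u) {
  ifelse(rbp_r + rbp_u == 0, 0, 2 * rbp_r * rbp_u / (rbp_r + rbp_u))
}

#' Evaluate a run with the understandability-aware RBP family
#'
#' Per query computes: RBP_r and RBP_u (binary relevance /
#' understandability gains) with residuals; uRBP, whose gain at each rank is
#' the product of the two binary gains (unassessed documents contribute 0;
#' the residual assumes they gain 1); MM_RBP; the condensed starred variants
#' computed on the run with unassessed documents deleted (ranks close up
#' before truncation at depth n); and Unj@n, the number of unassessed
#' documents among the top n retrieved. Queries present in the judgments
#' but with an empty ranking score 0 with residual 1.
#'
#' @param run a `trec_run`.
#' @param judg an `rr_judgments` data frame.
#' @param cfg an [eval_config()].
#' @return list with `per_query` (data frame, one row per query) and `mean`
#'   (named vector of arithmetic means over queries).
#' @export
evaluate_run <- function(run, judg, cfg = eval_config()) {
  stopifnot(inherits(run, "trec_run"), inherits(judg, "rr_judgments"))
  qids <- sort(union(unique(judg$qid), unique(run$qid)))
  p <- cfg$p; n <- cfg$n
  rows <- lapply(qids, function(q) {
    rq <- run[run$qid == q, , drop = FALSE]
    rq <- rq[order(rq$rank), , drop = FALSE]
    jq <- judg[judg$qid == q, , drop = FALSE]
    gv <- .rr_gain_vectors(rq, jq, cfg)
    rbp_r <- .rr_rbp(gv$r, p, n)
    rbp_u <- .rr_rbp(gv$u, p, n)
    urbp <- .rr_rbp(gv$r * gv$u, p, n)
    keep <- gv$assessed
    rbp_r_s <- .rr_rbp(gv$r[keep], p, n)
    rbp_u_s <- .rr_rbp(gv$u[keep], p, n)
    urbp_s <- .rr_rbp((gv$r * gv$u)[keep], p, n)
    data.frame(
      qid = q,
      rbp_r = rbp_r["value"], rbp_r_resid = rbp_r["residual"],
      rbp_u = rbp_u["value"], rbp_u_resid = rbp_u["residual"],
      urbp = urbp["value"], urbp_resid = urbp["residual"],
      mm_rbp = mm_rbp(rbp_r["value"], rbp_u["value"]),
      rbp_r_star = rbp_r_s["value"], rbp_u_star = rbp_u_s["value"],
      urbp_star = urbp_s["value"],
      mm_rbp_star = mm_rbp(rbp_r_s["value"], rbp_u_s["value"]),
      unj = sum(!gv$assessed[seq_len(min(n, nrow(rq)))]),
      stringsAsFactors = FALSE
    )
  })
  per_query <- do.call(rbind, rows)
  rownames(per_query) <- NULL
  means <- colMeans(per_query[, setdiff(names(per_query), "qid")])
  list(per_query = per_query, mean = means)
}

#' Correlations between estimates and assessments
#'
#' Pearson, Spearman (average ranks for ties) and Kendall (tau-b)
#' coefficients.
#'
#' @param estimates,assessments paired numeric vectors, length >= 3,
#'   neither constant.
#' @return named numeric vector `pearson`, `spearman`, `kendall`.
#' @export
correlations <- function(estimates, assessments) {
  if (length(estimates) != length(assessments))
    stop("paired vectors must have equal length")
  ok <- is.finite(estimates) & is.finite(assessments)
  x <- estimates[ok]; y <- assessments[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  c(pearson = cor(x, y, method = "pearson"),
    spearman = cor(x, y, method = "spearman"),
    kendall = cor(x, y, method = "kendall"))
}

#' Paired randomization test
#'
#' Two-sided sign-flip randomization test on per-query paired differences:
#' the observed mean difference is compared with its distribution under
#' 10,000 seeded random sign flips.
#'
#' @param per_query_a,per_query_b equal-length paired score vectors.
#' @param n_perm number of sign-flip samples (default 10000).
#' @param seed integer seed.
#' @return the p-value.
#' @export
paired_significance <- function(per_query_a, per_query_b, n_perm = 10000,
                                seed = 1L) {
  if (length(per_query_a) != length(per_query_b))
    stop("paired vectors must have equal length")
  d <- per_query_a - per_query_b
  if (all(d == 0)) return(1.0)
  obs <- abs(mean(d))
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                  nrow = n_perm)
  sim <- abs(flips %*% d) / length(d)
  (1 + sum(sim >= obs - 1e-12)) / (n_perm + 1)
}
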