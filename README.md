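# readrank

Health information on the Web is often written far above the reading level
of the people who need it. Search engines aimed at the general public
therefore need two things: a way to **estimate how understandable a page
is** from nothing but its HTML, and a way to **fold that estimate into
ranking** without giving up topical relevance. `readrank` implements both,
together with the evaluation measures needed to tell whether a ranker
actually surfaced results that are relevant *and* understandable. It is
aimed at researchers in consumer health search and at engineers building
health-focused search services.

## What it computes

**Understandability estimators.** From extracted page text the package
computes the eight classic readability formulae — ARI, Coleman-Liau (CLI),
Dale-Chall (DCI), Flesch-Kincaid grade (FKGL), Flesch Reading Ease (FRE),
Gunning Fog (GFI), LIX and SMOG — e.g.

    SMOG = 1.0430 * sqrt(polysyllables * 30 / sentences) + 3.1291

plus their raw components, medical-vocabulary features (affixes, keyword
dictionaries, scored consumer-vocabulary concepts, hierarchical concepts
where tree depth proxies difficulty), natural-language and HTML-tag
features, and corpus-derived word-frequency ranks (each word mapped to a
0–100 scale, 100 = most frequent). A machine-learning estimator projects
documents into a 10-dimensional latent semantic space (TF-IDF + truncated
SVD) and trains regressors/classifiers on three background corpora of
graded difficulty (lay forum = 1, encyclopedic = 2, biomedical literature
= 3), so a regressor's output is a difficulty score on that 1–3 scale.

Because readability formulae are sensitive to how text is pulled out of
HTML, extraction is explicit: a *naive* pipeline keeps all visible text, a
*boilerplate* pipeline drops navigation/template blocks, and the
*ForcePeriod* (FP) / *DoNotForcePeriod* (DNFP) heuristics decide whether
unpunctuated HTML fields (headings, cells, list items) are closed with a
period before sentence splitting.

**Ranking integration.** BM25 (b = 0.75, k1 = 1.2), reranking of the top
k ∈ {15, 20, 50} results by ascending estimated difficulty, reciprocal
rank fusion `score(d) = Σ 1/(60 + rank)`, and five learning-to-rank
labeling strategies combining relevance R with understandability U
(e.g. strategy 5 boosts easy-to-read documents: `F = 2R if U ≤ 40, else R`
on the 0–100 scale), trained with a pairwise gradient-boosted ranker over
24 IR features and the understandability feature set.

**Evaluation.** Rank-biased precision (p = 0.8, depth 10) in four flavors:
RBP_r (relevance gain), RBP_u (understandability gain, score ≤ 40 on the
0–100 scale), uRBP (product of the two gains), and their harmonic mean
MM_RBP; each with residuals for unassessed documents, condensed (starred)
variants that delete unassessed documents before scoring, and Unj@10.
Pearson/Spearman/Kendall correlations and a paired randomization test
support estimator and system comparisons.

A seeded synthetic-fixture generator emulates the study conditions
(three difficulty-graded corpora, HTML pages with planted structure and
difficulty tiers, graded relevance plus understandability judgments on the
5-point or 0–100 scale with a configurable relevance–understandability
correlation), so every component runs self-contained.

## Worked example

```r
library(readrank)

html <- paste0(
  "<html><head><title>Managing high blood pressure</title></head><body>",
  "<ul>", paste(rep('<li><a href="#">Home</a></li>', 30), collapse = ""), "</ul>",
  "<h1>What is hypertension</h1>",
  "<p>High blood pressure means your heart works harder than it should. ",
  "Many people feel fine and do not know they have it.</p>",
  "<p>Ask your doctor to check your blood pressure every year.</p>",
  "</body></html>")

doc <- extract_document(html, "bp-page", pipeline = "boilerplate", heuristic = "FP")
doc
#> <extracted_document bp-page: boilerplate+FP, 4 blocks, 226 chars>
```

The 30-link nav bar is classified as boilerplate and dropped; the title,
heading and paragraphs survive, and FP closes the unpunctuated title and
heading so they count as sentences:

```r
sc <- surface_counts(tokenize_text(doc$text))
round(readability_scores(sc), 3)
#>    ari    cli    dci   fkgl    fre    gfi    lix   smog
#>  4.571  7.996 10.096  4.093 79.610  4.146 20.621  5.684
```

FRE ≈ 80 and FKGL ≈ 4 say this reads at roughly a 4th-grade level — easy
text. DCI ≈ 10 is higher because the fixture common-word list is small, so
many words count as "difficult"; with the full Dale-Chall list loaded via
`surface_counts(tok, common_words = read_wordlist("dale_chall.txt"))` it
drops accordingly. Consumer-vocabulary matching finds the lay and the
technical name of the same condition, with their familiarity scores
(higher = more familiar to lay readers):

```r
m <- match_concepts(tokenize_text(doc$text), rr_resources()$chv)
m[, c("term", "score", "group")]
#>                  term score   group
#> 1 high blood pressure  0.83 disease
#> 2        hypertension  0.35 disease
#> 3 high blood pressure  0.83 disease
round(chv_features(m), 3)
#>  chv_count  chv_score_mean  ... chv_disease_score_mean
#>       3.00            0.67 ...                   0.67
```

For retrieval, `bm25_rank()` produces a TREC-style run over an indexed
collection, `rerank_topk(run, difficulty, k = 15)` reorders the top 15 by
ascending difficulty, `rrf_fuse()` merges a relevance run with a
difficulty-based one, and `evaluate_run(run, judgments)` returns the
RBP-family measures per query and averaged. See the vignette
(`vignettes/understandability-ranking.Rmd`) for the full pipeline,
including the latent-semantic estimators and learning to rank.

A command-line front end for shell pipelines ships in
`inst/scripts/readrank` (subcommands `extract`, `rank`, `rerank`, `fuse`,
`eval`, `generate`).

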