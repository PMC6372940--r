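---
title: "Estimating Web page understandability and using it in ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating Web page understandability and using it in ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readrank)
```

## The problem

People searching the Web for health advice routinely land on pages written
for clinicians. A health-focused search engine should prefer pages a lay
reader can actually use — but "understandability" has to be estimated from
the page itself, and the estimate has to be folded into ranking without
destroying topical relevance. `readrank` implements that whole chain:
estimators, preprocessing, ranking integration and evaluation. This
vignette explains the models, the tunable parameters, and the design
decisions, in the package's own terms.

## HTML preprocessing: pipelines and sentence-ending heuristics

Readability formulae depend on sentence boundaries, and HTML is full of
fields — titles, headings, list items, table cells — that carry no
terminal punctuation. Depending on how a page is flattened, those fields
are read either as many short sentences or as a few absurdly long ones,
and grade-level estimates move by several grades. The package therefore
makes preprocessing explicit along two axes:

* **Pipeline.** `"naive"` keeps every visible text block (script/style
  content is always discarded). `"boilerplate"` additionally removes
  blocks classified as boilerplate by a deterministic built-in rule: a
  block is boilerplate when more than half of its characters sit inside
  links, or when it is a very short (< 5 words) list/stray fragment. The
  thresholds are arguments of `extract_blocks()`; the classifier is
  deliberately simple so that its behavior is fully reproducible, and the
  block representation is the interface — a heavier content extractor can
  be substituted by filtering blocks before `assemble_text()`.
* **Heuristic.** ForcePeriod (`"FP"`) appends a period to each block that
  does not already end in one of `. ! ? : ;`; DoNotForcePeriod (`"DNFP"`)
  joins blocks unchanged. FP can only add sentence boundaries, so the FP
  sentence count always dominates the DNFP count — a property the test
  suite checks on random pages.

Block kinds are mapped from tag names (`h1`–`h6` → heading, `p` →
paragraph, `li`/`dt`/`dd` → list item, `td`/`th` → table cell, `title`,
else other); whitespace runs collapse to single spaces; element text only
is used (attributes and alt-text are ignored). Malformed HTML is parsed
best-effort and never raises.

## Surface statistics and the readability formulae

`tokenize_text()` splits sentences on terminal punctuation followed by
whitespace, with a small abbreviation list (Dr., Mr., e.g., i.e., ...)
suppressing false boundaries; words are maximal alphanumeric-plus-
apostrophe runs, case-folded. Syllables come from a bundled dictionary
(covering silent-e words and other irregulars) with a vowel-group fallback
floored at one — the dictionary-first design mirrors hyphenation-based
counting without binding to one hyphenation library. Two character counts
are kept because the formulae disagree: ARI counts letters+digits, CLI
letters only, each following its original definition.

The eight formulae (ARI, CLI, DCI, FKGL, FRE, GFI, LIX, SMOG) are direct
arithmetic on the surface counts; all are validated to 1e-9 against
hand-computed values on five frozen fixture texts. Polysyllables are words
of more than three syllables; difficult words are words absent from a
common-word list. The bundled ~220-word list is a compact stand-in for the
Dale-Chall 3000 list — absolute DCI values with the fixture list are
shifted upward (more words count as difficult), which is why comparisons
should either use the real list (loadable with `read_wordlist()`) or stay
within one configuration. Every raw feature is also emitted per word and
per sentence via `normalize_features()`; ratios are invariant under
document duplication, and the tests check that.

## Vocabulary, natural-language and HTML features

Concept mapping is deterministic greedy longest-match over the token
stream (case-insensitive, spans consumed so matches never overlap,
equal-length ties broken lexicographically). This replaces a full
concept-mapper: it is exact on its dictionary, reproducible, and the
`ConceptMatch` data frame is the interface if a richer mapper is wanted.
Scored consumer-vocabulary features average familiarity scores over all /
symptom / disease matches; hierarchical expert-vocabulary features average
tree depth, deeper concepts being presumed harder. Empty subsets yield
`NA` (missing), never zero — a zero would look like "very familiar" or
"very shallow" to a downstream model.

The bundled part-of-speech backend is closed-class lists plus suffix rules
with noun as the default open class; it supplies neither entities nor a
parse tree, so those two features are emitted as `NA` and consumers must
tolerate missing values (the boosted trees route missing values natively).
Sentiment counts use a small polarity lexicon — lay forum text is
measurably more emotional than biomedical prose, which is exactly the
signal the feature encodes. HTML tag counts are computed on the raw HTML,
never on extracted text, so they are identical across preprocessing
settings; the heading and list totals satisfy their sum identities by
construction.

## Word-frequency rank models

For each background corpus, words are sorted by descending frequency and
the word at position `pos` of vocabulary size `V` receives
`100 (V - pos + 1) / V`: common words near 100, rare words near 0.
Equal-frequency words share their tie group's first position (competition
ranking), which keeps the most frequent word at exactly 100 even when the
top frequency is tied and keeps values weakly monotone in frequency.
Documents are summarized by the 25th/50th/75th percentiles (linear
interpolation between order statistics, stated explicitly because
percentile conventions differ) and the mean of their per-token values —
token-level, so a repeated common word counts each time. Out-of-vocabulary
words are dropped by default; the "includes OV" mean instead scores them
as 0, the maximally-rare reading. A pooled model is built by concatenating
the three corpora's token streams.

## Latent-semantic estimators

The machine-learning estimators are trained on three labeled background
corpora: lay forum text (label 1), encyclopedic articles (2), biomedical
literature (3). Features are TF-IDF (natural term frequency; smoothed
idf `log((1+N)/(1+df)) + 1`; L2-normalized rows) projected onto the top
10 right singular vectors of the training matrix. The SVD is computed
densely and the sign of each component is fixed (largest-magnitude entry
positive), so a fit is bit-reproducible; unseen documents are projected
with the training vocabulary and idf, and a fully out-of-vocabulary
document maps to the zero vector but is still scored. Fitting LSA on the
background corpora only — rather than jointly with evaluation documents —
keeps the estimator honest about unseen pages.

The model zoo covers linear, MLP, random-forest, SVM and gradient-boosted
regressors, and logistic, MLP, random-forest, SVM, multinomial naive Bayes
and gradient-boosted classifiers, all with library-default
hyperparameters and a recorded seed. Regressors treat the labels {1,2,3}
as ordinal reals, so their output reads as a difficulty score (higher =
harder). Multinomial naive Bayes is written in-package (no installed
library provides the multinomial variant) and shifts features by the
global minimum so the count model is well defined on latent coordinates.
`cross_fit_predictions()` provides the 10-fold cross-fitting protocol used
for assessed documents: each document is scored by a model that never saw
its target, and a final model trained on everything scores unassessed
documents.

## Ranking integration

`bm25_rank()` scores with `idf = ln((N - df + 0.5)/(df + 0.5) + 1)` — the
+1-inside-log variant, chosen so weights cannot go negative — and the
defaults b = 0.75, k1 = 1.2. Ties break by document id everywhere, which
makes every ranking deterministic.

`rerank_topk()` reorders only the top k (15/20/50 studied; evaluation
depth is 10, so k = 15 is conservative) by ascending difficulty, original
rank breaking ties; deeper ranks are untouched. Documents without a
difficulty score sort last within the top k — treating "unknown" as
"hardest" is the cautious choice when the goal is promoting easy reading;
an `invert` flag accommodates estimators where higher means easier.

`rrf_fuse()` uses the conventional rank-fusion constant c = 60
(configurable); rank-based fusion is the right tool here because relevance
scores and difficulty estimates live on incomparable scales.

The five learning-to-rank labeling strategies combine relevance R and
understandability U: identity labels with IR-only or extended features
(LTR1/2), a proportional understandability penalty (LTR3), hard filtering
to easy-to-read documents (LTR4), and boosting easy-to-read documents
(LTR5: `F = 2R` when U passes the threshold, else `R`). Thresholds are
U ≥ 2 on the 5-point scale and U ≤ 40 on the 0–100 scale (0 = easiest).
The boundary is inclusive on both the labeling and the evaluation side for
consistency; the strict-inequality reading of the evaluation rule would
differ only at exactly U = 40. The ranker is a pairwise gradient-boosted
model (single-threaded, seeded, so reproducible); the 24 IR features are
four weighting models (BM25, TF-IDF, Dirichlet-smoothed language model,
query-term coverage) × three fields (title, body, whole document) × two
length normalizations (raw, divided by field length) — the count and the
fields follow the multifield learning-to-rank convention, the concrete
models being the package's own choice.

## Evaluation measures

All measures are rank-biased precision at persistence p = 0.8 and depth
n = 10 (matching shallow assessment pools). Gains are binary: relevance
gain 1 for grades ≥ 1 ("somewhat relevant" or better); understandability
gain 1 for score ≤ U on the 0–100 scale or the two easiest levels on the
5-point scale (direction configurable, default high = easy, since the
original direction of that scale is not fixed). uRBP multiplies the two
gains per rank, so uRBP ≤ min(RBP_r, RBP_u) always, with equality in the
second argument when every assessed document is understandable. MM_RBP is
the harmonic mean, zero when both sides are zero.

Unassessed documents score 0 in the plain measures; the residual assumes
they (and everything below the evaluation depth) gain 1, so value +
residual bounds every possible completion of the assessments — the p^n
tail is included in the residual, and the bound is verified by exhaustive
enumeration in the tests. Condensed (starred) variants delete unassessed
documents before truncation; Unj@10 counts unassessed documents among the
top 10 retrieved. Query means are arithmetic, and queries with no judged
documents still count (value 0, residual 1) rather than being silently
dropped. Correlations are Pearson, Spearman (average ranks) and Kendall
tau-b; the paired significance test is a two-sided seeded sign-flip
randomization with 10,000 resamples.

## The synthetic reference collection

The generator produces the study conditions the package is tested under.
Defaults: three background corpora of 60 documents; mean sentence lengths
8 / 14 / 22 words and emotional-word densities 0.10 / 0.04 / 0.01 for
tiers 1–3, with partially overlapping tier vocabularies (the hard tier is
synthesized from Greco-Latin morphemes, so its length and syllable
difficulty are controllable and lexicon hits can be planted exactly); 40
pages carrying a title, a 40-link navigation bar (ground-truth
boilerplate), headings, paragraphs, a list and a table, with structural
blocks losing their terminal punctuation with probability 0.7; 10 queries
with 12 judged documents each. Understandability scores on the 0–100
scale follow the page's planted tier through a bimodal transform
(`100 · pbeta(pnorm(1.4·z), ½, ½)`), mimicking slider assessments anchored
at an "average" midpoint. Relevance grades are cut from a latent that
mixes a topicality component (the standardized BM25 score) with an
easiness component whose weight is the configured correlation divided by
0.85 — compensating the attenuation introduced by cutting a continuous
latent into three grades, so the realized grade–easiness correlation lands
within ±0.1 of the configured value. The default correlation is −0.4:
relevant documents tend to be harder to read, which is the regime that
makes understandability-aware ranking worth having.

Two different study conditions are used for the end-to-end checks: the
reranking check runs at the default −0.4, where promoting easy documents
must raise RBP_u and pay in RBP_r; the learning-to-rank check runs at
+0.2 with 40 queries over 60 pages, the regime where understandable and
relevant documents coexist (under strong negative correlation no ranker
can surface documents that are both, and a pairwise ranker cannot be
trained on a handful of queries — the original studies trained on
hundreds). Problem sizes throughout (60-document corpora, 40–60 pages,
10–90 queries) were chosen as the smallest scales at which the effects are
stable across seeds.

What the generator does **not** emulate: real crawled HTML (scripts,
encodings, deep nesting), real vocabulary statistics (its Zipf tail is
short), assessor noise and disagreement, and licensed resources (the
bundled lexicons are ~50-term fixtures in the same file formats as real
CHV/MeSH/ICD exports). Passing tests therefore demonstrate correctness of
the machinery and the direction of the effects, not the absolute
correlation or effectiveness levels reported on licensed collections.

## Numerical and degenerate-input conventions

Empty HTML yields an empty document; documents with no words make the
readability formulae error (callers decide the default — the feature
matrix emits `NA`). Zero denominators in per-word/per-sentence variants
yield `NA` with the raw value kept. Empty concept-match subsets yield `NA`
means. An empty ranking for a judged query scores 0 with residual 1. All
stochastic components (generator, fold assignment, boosting, sign-flip
test) consume explicit seeds, and single-threaded boosting keeps model
fits bit-reproducible; the acceptance script derives every seed from its
`--seed` argument.

## Known limitations

The boilerplate classifier is a two-rule heuristic: it will keep template
text that is long and link-free, and drop legitimate short list items.
The POS backend under-counts verbs it has no suffix evidence for. The
syllable fallback miscounts some silent-e words not in the dictionary.
Multinomial naive Bayes on shifted latent features is a pragmatic
adaptation, not a textbook count model. None of these affect the ranking
and evaluation layers, which consume only the feature interface.
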