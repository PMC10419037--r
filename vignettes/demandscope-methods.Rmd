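---
title: "Topic-sentiment mining of short health-community comments: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic-sentiment mining of short health-community comments: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demandscope)
library(dplyr)
```

demandscope mines *information demands* and the emotions attached to them
from corpora of short user comments — the kind posted in online health
communities, where a typical document is one or two sentences asking about a
symptom, a test result, or a treatment. The pipeline has five stages:
preprocessing, LDA topic discovery with model selection, embedding-based
topic-vector refinement and document fusion, lexicon sentiment scoring, and
category-level demand/emotion analysis. This vignette explains each model,
its tunable parameters, and the design decisions taken where more than one
reasonable construction existed.

## Preprocessing

Raw comments arrive as JSONL or CSV records (`read_corpus()`). Cleaning
(`clean_text()`) strips markup tag spans, scheme-prefixed URLs, control
characters, Unicode punctuation/symbol characters, and digit-only tokens,
then collapses whitespace; the function is total and idempotent. Scraped
text needs no more than this — full DOM parsing is out of scope.
Tokenization is a named, pluggable strategy: tests and the synthetic
corpora use whitespace splitting; real Chinese text binds a dictionary
segmenter through the same deterministic contract, so nothing downstream
depends on the tokenizer. Whether numerals or Latin-script tokens should
survive segmentation of Chinese text is a corpus-specific call; dropping
digit-only tokens is this package's default because bare numbers
(dates, counts) carry no topical or emotional signal in short comments.
Stopwords are removed by exact match; documents left empty are dropped with
a logged count since they can contribute nothing to either topics or
sentiment. The vocabulary maps tokens to contiguous 0-based indices in
C-locale lexicographic order — a deliberately platform-independent ordering
so that runs reproduce bit-for-bit anywhere.

## LDA by collapsed Gibbs sampling

Documents are modeled by latent Dirichlet allocation: topic-word rows
$\phi_k \sim \mathrm{Dir}(\beta)$, document-topic rows
$\theta_m \sim \mathrm{Dir}(\alpha)$, each token's topic drawn from
$\theta_m$ and the word from $\phi_{z}$. Inference integrates $\phi$ and
$\theta$ out and resamples per-token assignments with the standard
collapsed conditional

$$p(z_{mn} = k \mid \cdot) \propto
  (n_{mk}^{-} + \alpha)\,\frac{n_{kw}^{-} + \beta}{n_{k}^{-} + V\beta},$$

returning the smoothed point estimates
$\hat\phi_{kw} = (n_{kw}+\beta)/(n_k+V\beta)$ and
$\hat\theta_{mk} = (n_{mk}+\alpha)/(n_m+K\alpha)$ from the final state.

Defaults are $\alpha = 1.0$, $\beta = 0.01$, and 1000 full sweeps. A fixed
sweep count rather than a convergence test keeps the chain deterministic
given its seed; no burn-in averaging is applied (the point estimate comes
from the final state). The sampler is written in C++ but draws from R's own
RNG stream, so a single `set.seed()`-style `seed` argument fixes the entire
chain portably. Correctness is tested two ways: count-conservation and
row-stochasticity invariants on every fit, and — the sharper check — on a
two-token corpus the long-chain empirical distribution over all $K^2$
assignment states is compared with the exactly enumerated collapsed
posterior (total variation below 0.02).

**Held-out documents.** Perplexity,
$\exp(-\sum \log \sum_k \theta_{dk}\phi_{kw} / N)$, needs a $\theta$ for
unseen documents; it is re-estimated by *fold-in* Gibbs sampling — 50
seeded sweeps with $\phi$ frozen — the standard approach, stated explicitly
so results are reproducible.

**Choosing K.** `select_k()` fits each candidate K for several replicates
(distinct derived seeds), records training perplexity and topic coherence,
and selects the K with the highest mean coherence, ties to the smallest K
(parsimony). Coherence is the UMass variant — corpus-internal document
co-occurrence counts with +1 smoothing, summed over ranked top-word pairs —
because it needs no external reference corpus and is deterministic given
the model and corpus. Two numerical notes: pairs whose denominator count is
zero are skipped and logged rather than propagating `-Inf`; and because of
the +1 smoothing the score is *not* invariant under document duplication
(the unsmoothed ratio would be), which the test suite pins down with exact
hand-computed values. Model screening uses 300 sweeps per candidate fit
(selection needs relative, not converged, scores); the final fit at the
selected K keeps the 1000-sweep default.

## Topic vectors and document fusion

A topic is summarized in embedding space by an *optimized topic vector*
$\mu'_k$. The initial vector is the $\phi$-weighted sum of the embeddings of
the topic's top-N words, unit-normalized. The refinement loop then
iterates, over those N words,

$$u_w \propto \phi_{kw}\,\max(0, \cos(e_w, \mu)), \qquad
  \mu \leftarrow \mathrm{normalize}\Big(\sum_w u_w e_w\Big),$$

until $1 - \cos(\mu_{\text{new}}, \mu_{\text{old}}) < \texttt{tol}$
(default $10^{-6}$, `max_iter` 100). This power-iteration-style rule uses
exactly the ingredients that define the refinement — topic weights, cosine
similarity, iteration — and is fully testable: the suite re-implements the
loop independently and requires agreement to $10^{-8}$. Negative cosines
are clipped at zero so the weights stay a probability distribution; if
every cosine is clipped the iterate falls back to $\phi$-only weights, with
a message. One honest caveat: the *mean weighted cosine* is guaranteed not
to decrease when $\mu$ is updated with the weights held fixed (for
unit-norm embeddings $\mu_{\text{new}}$ is the exact maximizer), but after
the weights are re-gated the combined quantity can dip slightly; the tests
assert the guaranteed per-update property and, on the fixed reference toy,
a fully non-decreasing trajectory.

Embeddings come from a pluggable provider contract — any deterministic
`token -> d-vector` map. Two providers ship: seeded hash-random unit
vectors (the default everywhere in tests; no training, no files) and a TSV
embedding table for vectors exported from an external contextual model.
Training or fine-tuning such a model is explicitly out of scope; the
contract is the boundary.

A document's fused representation adds four same-dimension vectors per
token — word embedding $e_w$, sinusoidal position encoding $\rho(pos)$,
document embedding $\delta$ (mean of the document's word embeddings), and
the topic vector $\mu'_{z}$ of the token's Gibbs assignment — and averages
over tokens. Design choices here: "+" is vector addition in a shared
dimension $d$ (concatenation was rejected to keep one $d$); $\mu'$ enters
per token via the token's assignment rather than once per document through
a $\theta$-weighted mixture (the per-token reading matches the fused
*word*-vector construction; the alternative is noted, not implemented);
and the position encoding is the all-sine variant
$\rho(p)_j = \sin(p / 10000^{(j-1)/d})$ with 0-based positions, so position
0 contributes nothing — which keeps the one-token worked example exactly
$2e_w + \mu'_z$. On planted corpora, fused vectors cluster by true topic
(higher within- than between-topic cosine), which is the property that
matters downstream.

Each document's *primary topic* is the argmax of its $\hat\theta$ row, ties
to the smallest index.

## The sentiment calculus

Sentiment uses a lexicon in the layout of the Dalian University of
Technology emotion ontology: 7 major categories (Joy, Good, Anger, Sadness,
Fear, Evil, Surprise) over 21 subcategories, intensity grades in
$\{1,3,5,7,9\}$, and polarity codes $\{0, 1, -1, 3\}$ (neutral, positive,
negative, ambivalent). An entry may carry a second (auxiliary) annotation.
Beware one sharp edge: the anger subcategory code is the literal string
`"NA"`, so every reader in this package treats empty fields — never the
text `NA` — as missing, and profile columns carry a `profile_` prefix.

A word's sentiment value in $\{-1, 0, 1\}$ is computed by rule:

* single annotation with polarity in $\{-1,0,1\}$: the polarity itself;
* two annotations with *identical* polarity: the first
  `[intensity, polarity]` pair decides;
* two ambivalent annotations (both polarity 3), each carrying a signed
  score $s \in [-4, 4]$: combine $c = s_{\text{prev}} + r\,s_{\text{next}}$
  with ratio $r = 0.75$ by default (the share given to the later
  annotation; configurable), then snap to whichever of $\{-1, 0, 1\}$ is at
  minimal absolute distance, exact ties resolving to 0;
* a mixed pair (one ambivalent, one not): the non-ambivalent annotation
  decides — the minimal-assumption fallback for a case the rule set leaves
  open.

The calculus satisfies and is tested for: negation symmetry (flipping every
polarity and score flips the value), monotonicity of the snap in $c$, and
the $r = 0$ degeneracy to `snap(s_prev)`. Sentences score as the sum of
`value * intensity` over exact-match lexicon hits (bag semantics; no
negation scope or intensifier handling — out of scope by design), and a
document's magnitude is the sum over its sentences, split on terminal
punctuation *before* cleaning removes it. Document polarity is the sign;
neutral documents are counted separately and excluded from
positive/negative percentages. Matching is exact token equality after
preprocessing, mirroring a dictionary-segmenter workflow; no stemming.
Emotion *profiles* sum the intensity of matched words per subcategory
(primary annotation only), giving each document a 21-dimension vector.

## Demand categories, polarity tables, correlation

Raw topics map to labeled demand categories through a user-supplied JSON
map — interpretation, not computation. `categorize()` reports counts and
proportions to two decimals; `polarity_distribution()` reports
`pct_pos = round(100 * n_pos / (n_pos + n_neg))` to the nearest integer
with `pct_neg = 100 - pct_pos`, the two printed formats these tables
conventionally use. Both are exact arithmetic and tested against fixed
count fixtures.

Topic-emotion association is Pearson correlation between the per-document
*category indicator* and each per-document emotion intensity — the only
construction that yields a category-by-subcategory matrix from per-document
data. Two-sided p-values come from the t transform on $M-2$ degrees of
freedom; constant columns are recorded as undefined and masked rather than
propagating `NaN`. The raw $p < 0.05$ threshold is the default for
fidelity to common practice in this literature; a Benjamini–Hochberg mode
is exposed for rigor. Both category granularities (raw topics or mapped
categories) are supported — the map decides.

One composition effect deserves emphasis: if an emotion is enriched in
category A, its intensity is automatically *depleted* in the indicator's
complement, so every planted (A, e) cell drags the (B, e) and (C, e) cells
negative. Those induced anti-correlations are mathematics, not errors;
recovery checks therefore count *positive*-significant cells as detections.

`relevance_top_words()` exports per-topic word rankings under
$\lambda \log \phi_{kw} + (1-\lambda)\log(\phi_{kw}/p_w)$ — the standard
interpolation between topic probability ($\lambda = 1$) and lift
($\lambda = 0$) used by interactive topic browsers; the interactive
visualization itself is out of scope, the CSV export is not.

## The synthetic-data generator

Because real health-community corpora are not redistributable, every stage
is validated on generated corpora with known ground truth. The generator
runs the LDA process forward with *block-structured* topics: each topic
owns a private contiguous vocabulary block holding `separation` of its
mass (flat Dirichlet within the block), the remainder spread by a
Dirichlet($\beta_{gen}$) draw over the full vocabulary. Defaults — 3
topics, V = 300, 200 documents of 50 tokens, separation 0.9,
$\alpha_{gen} = 0.1$, $\beta_{gen} = 0.1$ — emulate a desk-scale corpus of
short, mostly single-question comments: the small $\alpha_{gen}$
concentrates each document on one dominant topic, as real short comments
are, and 0.9 separation makes topics well-separated but not disjoint.

Emotion structure is planted independently: `inject_emotions()` *appends*
(never substitutes, so the topic and emotion signals stay independently
controllable) Binomial(L, rate) lexicon words per designed
(topic, subcategory) cell, positive with the topic's `polarity_mix`
probability. The default design is one-hot at rate 0.1 — about five
emotion words per matching document — and the default mix recycles
(0.63, 0.27, 0.56), the kind of spread real per-category positive shares
exhibit. The synthetic lexicon covers all 21 subcategories with ASCII
pseudo-words so tests are tokenizer-independent.

What the generator does *not* emulate: real lexical burstiness, document
length variation, Chinese morphology, sentence structure (generated
documents are bags), or correlated topics. Passing recovery tests
therefore demonstrates the *algorithms* are correct and well-calibrated on
the stated conditions — not that any particular real corpus will yield 36
interpretable topics.

## Evaluation harness

`classification_metrics()` computes per-class precision/recall with the
0-convention for empty denominators, macro-averages (micro averaging would
be dominated by the largest categories under realistic imbalance; the
averaging mode is a deliberate choice, stated here), and takes F1 as the
harmonic mean of macro precision and macro recall.
`crossvalidate()` runs seeded *stratified* k-fold validation — without
stratification the smallest categories would vanish from folds — around
any classifier satisfying the `function(train) -> function(test) -> labels`
contract. The package's own `lda_topic_classifier()` fits LDA on the
training fold, labels topics by majority training class, and classifies
held-out documents by fold-in. Both a 10-fold mode and a single holdout
split are possible through the same harness; neither is hard-wired into
model fitting.

## Problem sizes and numerical choices

The shipped test and acceptance runs use the generator defaults above
(10,000–13,000 tokens per corpus), 1000 Gibbs sweeps for final fits, 300
for K-screening across a 2–8 grid with 3 replicates, a 60,000-sweep chain
for the two-token posterior comparison, and 10-fold cross-validation at
500 sweeps per fold — sizes chosen so the whole suite runs in a few
minutes on one CPU while leaving each check statistically sharp.
Tie-breaks are fixed everywhere (smallest topic index, smallest K,
lexicographic term order, snap ties to 0) so identical inputs give
identical outputs on any platform.

## Known limitations

* Sentiment is lexicon-only: no negation scope, intensifiers, emoji, or
  machine-learned classifier.
* The ambivalent-combination rule is one consistent reading of a
  configurable two-annotation calculus; corpora annotated under different
  conventions may need a different `ratio` or a custom rule.
* Exhaustive topic matching in recovery studies is limited to K ≤ 8.
* UMass coherence depends on corpus scale through its +1 smoothing (see
  above); compare coherence values only within one corpus.
* The embedding providers shipped are deliberately training-free; semantic
  quality of $\mu'$ is bounded by the embeddings supplied.
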