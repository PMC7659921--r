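---
title: "Multi-interest dataset recommendation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-interest dataset recommendation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Functional-genomics repositories such as the Gene Expression Omnibus grow by
dozens of series per day, and most deposited datasets are analysed once and
never reused. A researcher rarely knows which of the 100 000+ series are
relevant to them, and keyword search only helps when they already know what
to look for. `midr` inverts the search: the *query is the researcher*,
embodied by their publication history, and datasets are ranked by how well
their metadata (title + summary) matches the researcher's interests.

The crucial modelling choice is that a researcher is not one interest.
An established scientist with, say, a dominant body of HIV work and a
smaller line of mouse-genomics papers is badly served by a single profile
vector: either the dominant interest swamps the ranking, or — for balanced,
dispersed interests — the mean vector lands at a "centroid" topic that
matches none of their actual interests (mouse genomics + HIV vaccines does
not imply an interest in mouse vaccines). `midr` therefore clusters the
publications into interests with a non-parametric mixture and issues one
query per interest.

## The vector space

Publications (title + abstract) and dataset records (title + summary) are
preprocessed identically: URLs removed, lower-cased, punctuation mapped to
spaces, stopwords dropped, tokens shorter than two characters or purely
numeric dropped, and tokens lemmatized to root forms. Both corpora are then
embedded in one TF-IDF space over unigrams and bigrams (`ngram_max = 2`;
higher orders mostly add sparsity). We fit the vocabulary on the *union* of
the two corpora, because the ranking in equation (3) below only makes sense
if researcher and dataset vectors are comparable; fitting on either corpus
alone would silently drop the other's discriminative terms. The IDF is the
smoothed logarithmic variant

$$\mathrm{idf}(w) = \ln\frac{1 + n_{\text{docs}}}{1 + \mathrm{df}(w)} + 1,$$

with `min_df = 2` (singleton terms carry more noise than signal in
metadata-length texts), and every document vector is unit-normalized.

A researcher $r$ with papers $P_r$, $N_r = |P_r|$, is the recency-weighted
mean of their paper vectors:

$$v_r = \frac{1}{N_r}\sum_{p \in P_r} \lambda_p\, v_p,
\qquad \lambda_p = e^{-k t_p},$$

where $t_p$ is the age of paper $p$ in years relative to a reference year
and $k = 0.05$ per year, so a ten-year-old paper contributes
$e^{-0.5} \approx 0.61$ of a current one. The reference year defaults to
the newest publication year in the profile, which keeps results
reproducible for a frozen profile; set `reference_year` to the wall-clock
year if you want a stored profile to keep ageing. A *cluster vector* (the
"pseudo-researcher" for one interest) is the same construction restricted
to one cluster's papers, with $N$ the cluster size. Datasets are ranked by
cosine similarity,

$$\mathrm{sim}(r, d) = \cos(v_r, v_d),$$

which is in $[0, 1]$ because TF-IDF weights are non-negative.

## Interest clustering

Papers are clustered on **bag-of-word counts** (not TF-IDF — the mixture is
a multinomial model of token counts; the TF-IDF vectors are used afterwards
to build cluster queries) with a Dirichlet-process multinomial mixture
sampled by collapsed Gibbs. Each sweep removes every document in turn and
reassigns it with probability proportional to

* existing cluster $z$: $m_z \cdot L(d \mid z; \beta)$,
* new cluster: $\gamma_{\text{new}} \cdot L(d \mid \varnothing; \beta)$,

where $m_z$ is the cluster size and $L$ the collapsed Dirichlet-multinomial
predictive with per-word pseudo-count $\beta$.

**What the user-facing α means.** The package exposes a single
concentration-like knob `alpha` and maps it to the word pseudo-count
$\beta$, with the Chinese-restaurant new-table weight $\gamma_{\text{new}}$
kept separate (default 1). In an orthodox CRP the concentration parameter
*increases* the number of clusters, but the behaviour this system relies on
— and the behaviour users observe — is the inverse: larger α flattens the
word likelihood, makes documents look exchangeable, and merges clusters.
Treating α as the smoothing pseudo-count is the standard mechanism that
produces that inverse relation, and both knobs remain available in the
configuration for users who want the orthodox reading.

**The α rule.** More publications imply more interests, so α must shrink —
but stabilize — with profile size:

$$\alpha = \frac{10}{\sqrt{N}}.$$

`propose_alpha()` keeps full precision internally; displays round to two
decimals.

**Initialization.** The sampler seats documents sequentially at start-up:
each document joins an existing cluster or opens a new one using exactly
the collapsed predictive above, starting from an empty state. We chose this
over starting with all documents in one cluster because the single-site
Gibbs kernel has no split move: from an all-in-one start the chain must
route documents through improbable singleton states to separate merged
topics, and in practice it stalls — on a 4-topic corpus with disjoint
vocabularies it recovered the partition at adjusted Rand index 0.71 on
every seed, versus 1.0 from seated starts. Sequential seating uses no extra
machinery and keeps the run deterministic given the seed.

**Convergence and determinism.** At most `n_iter = 50` sweeps, stopping
early once fewer than 2% of documents change cluster in a sweep (on
interest-sized profiles the chain typically settles within a handful of
sweeps). The reported partition is the final state, not a posterior
summary: it is reproducible and is what downstream stages consume. Ties in
assignment probabilities resolve to the lowest cluster id; all RNG flows
from one integer seed.

**Singleton pruning.** Clusters with one paper are too thin to estimate an
interest and are dropped from the recommendation-eligible set (the paper
stays visible in diagnostics). If *every* cluster is a singleton the
`fallback` flag tells callers to revert to the baseline researcher vector.

**Baseline comparison.** `kmeans_cluster()` wraps `stats::kmeans` over the
TF-IDF vectors for fixed-k comparisons (the cohesion metrics below); it is
a comparator, never part of the recommendation path.

## Recommendation modes

* **baseline** — one ranked list from $v_r$.
* **midr** — one list per eligible cluster, merged round-robin: clusters
  ordered by size descending (ties: lower id), one item taken from each in
  turn, accessions already emitted are skipped, stop at `top_k`. Size
  ordering is deterministic and lets stronger interests lead the list.
* **midr_separate** — the per-cluster lists reported separately.

Before merging or reporting, each cluster passes a relevance filter: if the
mean similarity of its top (at most 10) datasets is ≤ 0.05, the cluster is
suppressed. This removes interests that the indexed repository simply does
not cover (e.g. a statistical-methodology cluster queried against an
expression-data index), which would otherwise fill their list with
uniformly irrelevant items. Suppression applies at exactly the threshold;
an empty ranking is always suppressed. Zero query vectors (a cluster whose
terms are all out-of-vocabulary) warn and return an empty list rather than
raising, so batch runs survive degenerate clusters.

## Evaluation metrics

Ratings use a three-star scale (1 = not relevant, 2 = partially relevant,
3 = most relevant), converted linearly to gains 0/1/2. NDCG@k uses the
linear-gain form

$$\mathrm{NDCG}@k = \frac{\sum_{i=1}^{k} \frac{g_i}{\log_2(i+1)}}
{\sum_{i=1}^{k} \frac{g^{\downarrow}_i}{\log_2(i+1)}},$$

with $g^{\downarrow}$ the gains sorted descending — not the exponential
$2^{g}-1$ variant. A list with no relevant item at all is a 0/0 case; we
define it as NDCG 0 and flag it `degenerate`. This is deliberately
conservative: under the convention where such lists score near 1, an
out-of-scope cluster rated all-1-star inflates the mean NDCG while its
P@10 is 0, which is exactly the pathology the 0.05 suppression threshold
exists to remove. P@10 strict counts only 3-star items, partial counts 2-
and 3-star, and the denominator is always k (missing ratings are not
relevant), so strict ≤ partial always. In separate mode, per-cluster
metrics are averaged unweighted per researcher.

Clustering quality is measured by cohesion: IACCS (mean pairwise cosine of
per-paper term-count vectors within a cluster, averaged over clusters with
≥ 2 papers) and ICCS (mean pairwise cosine between clusters' concatenated
term lists). Raw counts with multiplicity, no idf — the metric compares
term lists, not weighted embeddings; either preprocessed words or MeSH
terms can serve as the list. Good partitions have high mean IACCS and low
ICCS.

## Term normalization by embedding neighborhoods

Sparse biomedical text scatters one concept over many surface forms
(HIV, HIV-1, HIV/AIDS, AIDS). `build_word_groups()` links each term to its
top-5 embedding neighbors at cosine ≥ 0.70, takes connected components as
word groups, and rewrites every member to the group's most corpus-frequent
term (ties: lexicographic). Components are used because they are
deterministic and order-independent; the score cutoff exists because an
unconditioned top-5 graph over-merges on small corpora. Normalization is
applied to *both* publication and dataset texts, so replaced terms remain
comparable across the shared vector space. The embedding itself is a
count-based model — positive PMI co-occurrence (symmetric window, default
5) factorized by truncated SVD to unit-normalized word vectors — which is
fully deterministic, needs no iteration budget, and is adequate for
neighbor queries at the corpus sizes this package targets. Pre-trained
vectors in the standard one-term-per-line text format can be loaded with
`read_embedding()` instead. Training corpora can be year-filtered (e.g.
dropping pre-1998 articles to match the microarray era) via `min_year`.

The lemmatizer behind `preprocess()` is pluggable; the default is a small
dictionary + rule English noun lemmatizer (irregulars, conservative plural
stripping). The contract is "root forms", not a specific tool — pass any
`function(tokens)` for a different language or a heavier lemmatizer.

## The synthetic world

`simulate_world()` generates the fixture every stage is tested on: topics
are multinomials concentrating mass $1-\text{overlap}$ on disjoint term
blocks (random within-block weights) plus a uniform shared mass; papers and
dataset documents are i.i.d. draws from their topic. The default world has
4 topics over 400 terms (overlap 0.02), 60-token documents, 30 datasets
each for topics 1–3 and *none* for topic 4, and one researcher with 10/9/8
papers on topics 1, 2 and 4 — so the pipeline must both recover the three
interests and suppress the dataset-free one via the 0.05 threshold. These
sizes run the full pipeline in seconds.

Documents are generated directly as token lists (the post-preprocessing
representation), so the generator is independent of the lemmatizer;
title/abstract strings assembled from the tokens support I/O round trips.
What the generator does *not* emulate: real GEO/PubMed term distributions
(Zipfian tails, boilerplate), MeSH ontology structure, topic correlation,
author-specific style, or noisy metadata. Passing tests on this fixture
show the machinery is correct and the method behaves as designed under
planted structure — not that real-world ranking quality matches any
particular published figure, which depended on private corpora and human
ratings.

Two test fixtures deserve a note. The cluster-recovery fixture uses
disjoint vocabularies (overlap 0), 20 documents per topic — separable by
construction, so failure indicates a sampler defect, not a hard corpus.
The α-trend fixture (10 topics, 100 documents) instead uses short 20-token
documents with overlap 0.35: on well-separated corpora the mixture finds
the true 10 clusters at every α in {0.3, …, 10} and the inverse α–cluster
relation is invisible; short overlapping documents give the smoothing room
to merge, and the median cluster count falls 10 → 8 → 5 → 4 → 3 across the
grid.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log space via `lgamma`; assignment sampling
  normalizes by the max log-probability.
* Cluster ids are compacted to 1..K in order of first appearance; ranking
  ties break by accession ascending; representative ties break
  lexicographically — every tie-break is deterministic.
* Unit norms are cached implicitly by normalizing at construction; zero
  vectors are represented as empty named vectors and propagate as
  warnings, not errors.
* `kmeans_cluster` with k = n seeds every point as its own center under
  Lloyd's algorithm (the default algorithm requires k < n).
* Title matching is exact on a canonical form (lower-case, non-alphanumeric
  → space, squeezed); Unicode letters are kept and lower-cased. A
  single-character typo in the CV therefore rejects a publication — the
  accepted failure mode of plain string matching; an opt-in
  `max_typo_distance` relaxes it.

## Known limitations

* The DPMM reports one partition, not posterior uncertainty; no split-merge
  moves, no hyperparameter sampling, one cluster per paper.
* The recommender is purely content-based: no collaborative signal, no
  feedback loop, no handling of datasets with empty or boilerplate
  summaries beyond what TF-IDF tolerates.
* The lemmatizer is an intentionally small noun-oriented default; heavy
  morphological variation (verb forms, Greek/Latin plurals beyond the
  exception list) passes through unlemmatized.
* Cold-start remains for researchers with few or no indexed publications —
  the profile simply has little signal; the baseline mode degrades more
  gracefully than the clustered modes there (singleton pruning will often
  trigger the baseline fallback).
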