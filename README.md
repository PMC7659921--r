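# midr — multi-interest dataset recommendation from researcher publications

`midr` recommends repository dataset records to researchers, using the
researcher's own publications as the query. It was built around GEO-style
series metadata (accession, title, summary, submission date, linked PMIDs)
and PubMed-style publication records (PMID, title, abstract, year, MeSH
terms), but any corpus in those shapes works. The package is aimed at
people building scholarly recommender or dataset-discovery tooling, and at
anyone who wants a fully reproducible, desk-scale implementation of
content-based dataset recommendation with multi-interest user profiles.

## The model

Publications and dataset metadata live in one TF-IDF space (unigrams +
bigrams, smoothed log idf, unit-normalized vectors). A researcher *r* with
papers *P_r* is the recency-weighted mean of their paper vectors

    v_r = (1 / N_r) * Σ_{p ∈ P_r} λ_p v_p,    λ_p = exp(−k t_p),  k = 0.05,

and datasets *d* are ranked by cos(v_r, v_d). Because a single mean vector
collapses a multi-interest researcher onto their dominant (or centroid)
topic, the publications are first partitioned into interests with a
Dirichlet-process multinomial mixture (collapsed Gibbs on word counts),
with the concentration-like smoothing parameter set from the profile size,

    α = 10 / sqrt(N),

single-paper clusters pruned, one "pseudo-researcher" vector built per
cluster, and per-cluster rankings either shown separately or merged
round-robin. Clusters whose mean top-10 similarity is ≤ 0.05 are suppressed
as out of the repository's scope. Rankings are evaluated with NDCG@10
(linear gains from a 1–3 star scale) and P@10 strict/partial; clusterings
with intra-/inter-cluster cosine cohesion (IACCS/ICCS). The methods
vignette (`vignettes/multi-interest-recommendation.Rmd`) derives and
motivates every piece.

## Worked example

Everything below runs in a few seconds on the built-in synthetic world:
4 planted topics, 90 datasets (none for topic 4), and one researcher with
10 / 9 / 8 papers on topics 1, 2 and 4.

```r
library(midr)

world  <- simulate_world(seed = 7)
pubs   <- world$profile$publications
model  <- fit_tfidf(c(world$datasets$tokens, pubs$tokens), min_df = 2)
index  <- build_index(world$datasets, model, lemmatizer = identity)
paper_vecs <- lapply(pubs$tokens, vectorize, model = model)

clusters <- prune_singletons(
  dpmm_cluster(pubs$tokens, alpha = propose_alpha(nrow(pubs)), seed = 1))
clusters
#> <cluster_set> dpmm: 27 docs in 3 clusters (sizes 10, 9, 8)
```

The mixture recovers the three planted interests exactly (α = 1.92 from
the 27-paper rule). One query vector per cluster, then the merged
multi-interest recommendation:

```r
cvecs <- lapply(clusters$eligible, function(id) {
  sel <- clusters$assignments == id
  cluster_vector(paper_vecs[sel], pubs$year[sel])
})
names(cvecs) <- clusters$eligible

bundle <- recommend_midr(index, cvecs,
                         cluster_sizes = clusters$sizes[as.character(clusters$eligible)])
bundle
#> <recommendation_bundle> mode midr: 2 cluster list(s), 10 merged items, 1 suppressed

head(tidy(bundle)[, 1:5], 6)
#> # A tibble: 6 × 5
#>   list   source_cluster  rank accession score
#>   <chr>  <chr>          <int> <chr>     <dbl>
#> 1 merged 1                  1 SYN000016 0.558
#> 2 merged 2                  2 SYN000051 0.537
#> 3 merged 1                  3 SYN000028 0.549
#> 4 merged 2                  4 SYN000038 0.513
#> 5 merged 1                  5 SYN000018 0.540
#> 6 merged 2                  6 SYN000060 0.508
```

The topic-4 cluster was suppressed (its interest has no datasets in the
index, so its mean top-10 similarity falls below the 0.05 threshold), and
the merged list interleaves the two surviving interests — largest cluster
first — instead of letting the dominant one fill all ten slots. Rating the
merged list with the label oracle (topic 1 relevant, topic 2 adjacent):

```r
stars <- oracle_rate(bundle$merged, world$dataset_labels,
                     cluster_topic = 1L, adjacent = 2L)
metric_report(stars)
#> # A tibble: 1 × 3
#>   ndcg_at_k p_at_k_partial p_at_k_strict
#>       <dbl>          <dbl>         <dbl>
#> 1     0.943              1           0.5
```

Every item is at least partially relevant (partial P@10 = 1); strict P@10
is 0.5 because half the interleaved list comes from the adjacent topic.

Real corpora enter through `read_datasets()` / `read_publications()`
(JSONL or TSV), `match_publications()` (CV title matching), and the staged
`run_pipeline()` / `inst/cli/midr` command-line interface
(`simulate → index → profile → cluster → recommend → evaluate`).

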