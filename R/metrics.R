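#' Convert star ratings to gains
#'
#' The three-point rating scale (1 = not relevant, 2 = partially relevant,
#' 3 = most relevant) maps linearly to gains 0, 1, 2.
#'
#' @param stars Integer vector with values in {1, 2, 3}.
#' @return Integer gain vector.
#' @export
gains <- function(stars) {
  if (length(stars) < 1L || !all(stars %in% 1:3))
    abort("Ratings must be a non-empty vector over {1, 2, 3}.")
  as.integer(stars) - 1L
}

#' Normalized discounted cumulative gain at k
#'
#' `DCG = sum_i gain(i) / log2(i + 1)` over the first `min(k, n)` positions
#' with linear gains ([gains()]); the ideal DCG uses the same gains sorted
#' descending; NDCG is their ratio. A list with no relevant item at all
#' (all gains zero) is defined as NDCG 0 and flagged via the `degenerate`
#' attribute — the conservative reading of the 0/0 case.
#'
#' @param stars Integer star ratings in rank order.
#' @param k Cutoff (default 10).
#' @return NDCG in [0, 1].
#' @export
ndcg_at_k <- function(stars, k = 10L) {
  g <- gains(stars)
  m <- min(k, length(g))
  disc <- 1 / log2(seq_len(m) + 1)
  dcg <- sum(g[seq_len(m)] * disc)
  idcg <- sum(sort(g, decreasing = TRUE)[seq_len(m)] * disc)
  if (idcg == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  dcg / idcg
}

#' Precision at k (strict and partial)
#'
#' Strict counts only 3-star items in the top `k`; partial counts 2- and
#' 3-star items. The denominator is always `k`: positions without a rating
#' count as not relevant.
#'
#' @param stars Integer star ratings in rank order.
#' @param k Cutoff (default 10).
#' @param mode `"partial"` or `"strict"`.
#' @return Precision in [0, 1].
#' @export
p_at_k <- function(stars, k = 10L, mode = c("partial", "strict")) {
  mode <- match.arg(mode)
  if (length(stars) < 1L || !all(stars %in% 1:3))
    abort("Ratings must be a non-empty vector over {1, 2, 3}.")
  top <- head(stars, k)
  hits <- if (mode == "strict") sum(top == 3L) else sum(top >= 2L)
  hits / k
}

#' Metric report for one rated list
#'
#' @param stars Integer star ratings in rank order.
#' @param k Cutoff (default 10).
#' @return One-row tibble: `ndcg_at_k`, `p_at_k_partial`, `p_at_k_strict`.
#' @export
metric_report <- function(stars, k = 10L) {
  tibble(ndcg_at_k = as.numeric(ndcg_at_k(stars, k)),
         p_at_k_partial = p_at_k(stars, k, "partial"),
         p_at_k_strict = p_at_k(stars, k, "strict"))
}

#' Average per-cluster metric reports (separate mode)
#'
#' In separate mode each cluster is rated on its own list; the researcher's
#' final score is the unweighted mean over clusters.
#'
#' @param reports Tibble of per-cluster rows with numeric columns
#'   `ndcg_at_k`, `p_at_k_partial`, `p_at_k_strict` (e.g. stacked
#'   [metric_report()] rows).
#' @return One-row tibble of column means.
#' @export
average_separate <- function(reports) {
  if (nrow(reports) == 0L) abort("No cluster reports to average.")
  dplyr::summarise(reports,
                   dplyr::across(c("ndcg_at_k", "p_at_k_partial", "p_at_k_strict"),
                                 mean))
}

#' Intra-cluster cosine similarity (IACCS)
#'
#' Mean cosine similarity over all pairs of papers in one cluster, computed
#' on raw term-count vectors of each paper's term list (preprocessed
#' title + abstract words, or MeSH terms — whichever list is supplied; terms
#' are counted with multiplicity, no idf). Higher values mean a more
#' coherent cluster.
#'
#' @param term_lists List of character vectors, one per paper in the
#'   cluster.
#' @return Mean pairwise cosine in [0, 1]; `NA` with a warning for clusters
#'   of fewer than two papers.
#' @export
iaccs <- function(term_lists) {
  n <- length(term_lists)
  if (n < 2L) {
    warn("IACCS is undefined for clusters of fewer than 2 papers.")
    return(NA_real_)
  }
  vecs <- lapply(term_lists, count_vector)
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p) cosine_named(vecs[[p[1]]], vecs[[p[2]]])))
}

#' Inter-cluster cosine similarity (ICCS)
#'
#' Each cluster is represented by the concatenated term list of all its
#' papers; ICCS is the mean cosine similarity over all cluster pairs (raw
#' term counts, as in [iaccs()]). Lower values mean better-separated
#' clusters.
#'
#' @param clusters List of clusters, each a list of per-paper character
#'   vectors.
#' @return Mean pairwise cosine in [0, 1]; `NA` with a warning for fewer
#'   than two clusters.
#' @export
iccs <- function(clusters) {
  n <- length(clusters)
  if (n < 2L) {
    warn("ICCS is undefined for fewer than 2 clusters.")
    return(NA_real_)
  }
  vecs <- lapply(clusters, function(cl) count_vector(unlist(cl, use.names = FALSE)))
  pairs <- utils::combn(n, 2)
  mean(apply(pairs, 2, function(p) cosine_named(vecs[[p[1]]], vecs[[p[2]]])))
}

#' Mean IACCS over the eligible clusters of a partition
#'
#' Averages [iaccs()] over clusters with at least two papers; singleton
#' clusters are excluded from the mean.
#'
#' @param clusters List of clusters, each a list of per-paper character
#'   vectors.
#' @return Unweighted mean IACCS; `NA` with a warning when no cluster is
#'   eligible.
#' @export
mean_iaccs <- function(clusters) {
  eligible <- clusters[vapply(clusters, length, integer(1)) >= 2L]
  if (length(eligible) == 0L) {
    warn("No cluster with >= 2 papers; mean IACCS is undefined.")
    return(NA_real_)
  }
  mean(vapply(eligible, iaccs, numeric(1)))
}

#' Cluster-cohesion report for a clustered profile
#'
#' Convenience wrapper computing mean IACCS and ICCS for a partition of a
#' publication tibble, using either preprocessed title + abstract words or
#' MeSH terms as the per-paper term list.
#'
#' @param publications Publication tibble (as from [read_publications()]).
#' @param assignments Integer cluster id per publication.
#' @param mode `"words"` (preprocessed title + abstract) or `"mesh"`.
#' @param stopwords,lemmatizer Passed to [preprocess()] in words mode.
#' @return One-row tibble: `mode`, `mean_iaccs`, `iccs`, `n_clusters`.
#' @export
cluster_cohesion <- function(publications, assignments,
                             mode = c("words", "mesh"),
                             stopwords = default_stopwords(),
                             lemmatizer = lemmatize_en) {
  mode <- match.arg(mode)
  term_lists <- if (mode == "words") {
    preprocess(paste(publications$title, publications$abstract),
               stopwords = stopwords, lemmatizer = lemmatizer)
  } else {
    publications$mesh_terms
  }
  ids <- sort(unique(assignments))
  clusters <- lapply(ids, function(id) term_lists[assignments == id])
  tibble(mode = mode,
         mean_iaccs = mean_iaccs(clusters),
         iccs = if (length(clusters) >= 2L) iccs(clusters) else NA_real_,
         n_clusters = length(clusters))
}
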