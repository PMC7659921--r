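# a tiny index whose dataset vectors are controlled through one-term documents
toy_index <- function() {
  tokens <- list(c("tt1", "tt1", "uu"), c("tt2", "tt2", "uu"), c("tt3", "tt3", "uu"),
                 c("tt4", "tt4", "uu"), c("tt5", "tt5", "uu"))
  datasets <- tibble::tibble(
    accession = paste0("DS", 1:5),
    title = paste("dataset", 1:5),
    summary = vapply(tokens, paste, character(1), collapse = " "),
    submission_date = as.Date("2019-01-01") + 1:5,
    pmids = rep(list(integer(0)), 5)
  )
  model <- fit_tfidf(tokens, min_df = 1, ngram_max = 1)
  build_index(datasets, model, lemmatizer = identity)
}

test_that("rank_datasets orders by cosine with deterministic tie-breaks", {
  idx <- toy_index()
  v1 <- vectorize(c("tt1", "tt1", "uu"), idx$model)
  top <- rank_datasets(idx, v1, top_k = 3)
  expect_equal(top$accession[1], "DS1")
  expect_equal(top$score[1], 1, tolerance = 1e-9)
  expect_true(all(diff(top$score) <= 1e-12))

  # query orthogonal to the distinguishing terms ties everything: accession order
  vu <- c(uu = 1)
  all5 <- rank_datasets(idx, vu, top_k = 5)
  expect_equal(all5$accession, paste0("DS", 1:5))
  expect_true(all(abs(diff(all5$score)) < 1e-12))

  expect_warning(none <- rank_datasets(idx, setNames(numeric(0), character(0))),
                 "Zero query")
  expect_equal(nrow(none), 0L)
  expect_error(rank_datasets(idx, v1, top_k = 0), "top_k")
})

test_that("rank_datasets matches an exhaustive cosine scan on hand-built vectors", {
  idx <- toy_index()
  query <- c(tt1 = 0.5, tt3 = 0.8, u = 0.33)
  mine <- rank_datasets(idx, query, top_k = 5)
  ref <- vapply(seq_len(5), function(j) {
    col <- idx$matrix[, j]
    brute_cosine(query, setNames(as.numeric(col), rownames(idx$matrix)))
  }, numeric(1))
  ord <- order(-ref, idx$records$accession)
  expect_equal(mine$accession, idx$records$accession[ord])
  expect_equal(mine$score, ref[ord], tolerance = 1e-9)
  expect_true(all(mine$score >= 0 & mine$score <= 1))
})

test_that("round-robin merging interleaves by cluster size and dedupes", {
  idx <- toy_index()
  # cluster 1 prefers t1 > t2 > t3, cluster 2 prefers t4 > t5
  cvecs <- list(`1` = c(tt1 = 1, tt2 = 0.8, tt3 = 0.6),
                `2` = c(tt4 = 1, tt5 = 0.7))
  sizes <- c(`1` = 3L, `2` = 2L)
  bundle <- recommend_midr(idx, cvecs, cluster_sizes = sizes, top_k = 10)
  expect_equal(bundle$merged$accession[1:5], c("DS1", "DS4", "DS2", "DS5", "DS3"))
  expect_equal(bundle$merged$rank, 1:5)
  expect_true(all(diff(order(match(
    bundle$merged$accession[bundle$merged$source_cluster == "1"],
    bundle$per_cluster[["1"]]$accession))) > 0))  # subsequence property

  # one cluster: merged equals that cluster's list
  solo <- recommend_midr(idx, cvecs[1], cluster_sizes = sizes[1], top_k = 10)
  expect_equal(solo$merged$accession, solo$per_cluster[["1"]]$accession)

  expect_error(recommend_midr(idx, list()), "eligible")
})

test_that("duplicates across cluster lists are emitted once, first occurrence wins", {
  idx <- toy_index()
  cvecs <- list(`1` = c(tt1 = 1, tt2 = 0.5), `2` = c(tt1 = 1, tt3 = 0.5))
  bundle <- recommend_midr(idx, cvecs, cluster_sizes = c(`1` = 2L, `2` = 2L),
                           top_k = 4)
  expect_equal(anyDuplicated(bundle$merged$accession), 0L)
  expect_equal(bundle$merged$accession[1], "DS1")
  expect_equal(bundle$merged$source_cluster[1], "1")
  expect_false("DS1" %in% bundle$merged$accession[bundle$merged$source_cluster == "2"])
})

test_that("the relevance threshold suppresses weak clusters at the boundary", {
  expect_false(cluster_relevance_keep(rep(0.05, 10)))          # mean exactly 0.05
  expect_true(cluster_relevance_keep(rep(0.051, 10)))
  expect_false(cluster_relevance_keep(numeric(0)))
  expect_true(cluster_relevance_keep(c(0.2, 0.01)))
})

test_that("separate mode keeps per-cluster lists and reports suppressed clusters", {
  idx <- toy_index()
  cvecs <- list(`1` = c(tt1 = 1, tt2 = 0.8, tt3 = 0.6),
                `2` = c(tt4 = 1, tt5 = 0.7),
                `3` = c(zzz = 1))  # no overlap with the index vocabulary
  sizes <- c(`1` = 3L, `2` = 2L, `3` = 2L)
  suppressWarnings({
    sep <- recommend_midr_separate(idx, cvecs, cluster_sizes = sizes, top_k = 3)
    mrg <- recommend_midr(idx, cvecs, cluster_sizes = sizes, top_k = 3)
  })
  expect_null(sep$merged)
  expect_equal(sep$suppressed_clusters, "3")
  expect_false("3" %in% names(sep$per_cluster))
  expect_equal(sep$per_cluster, mrg$per_cluster)
  expect_true(all(vapply(sep$per_cluster, nrow, integer(1)) <= 3L))
})

test_that("baseline follows the dominant interest while midr covers both", {
  fx <- imbalance_fixture(n_a = 9L, n_b = 3L)
  pubs <- fx$profile$publications
  pv <- researcher_vector(fx$paper_vecs, pubs$year)
  base <- recommend_baseline(fx$index, pv, top_k = 10)
  base_topics <- unique(fx$dataset_labels[base$merged$accession])
  expect_equal(base_topics, 1L)

  cvecs <- lapply(1:2, function(t) {
    sel <- fx$paper_labels == t
    cluster_vector(fx$paper_vecs[sel], pubs$year[sel])
  })
  names(cvecs) <- 1:2
  midr_bundle <- recommend_midr(fx$index, cvecs,
                                cluster_sizes = c(`1` = 9L, `2` = 3L),
                                top_k = 10)
  midr_topics <- unique(fx$dataset_labels[midr_bundle$merged$accession])
  expect_setequal(midr_topics, c(1L, 2L))

  # single-paper baseline equals ranking that paper's vector
  one <- recommend_baseline(fx$index, researcher_vector(fx$paper_vecs[1], pubs$year[1]))
  direct <- rank_datasets(fx$index, fx$paper_vecs[[1]], top_k = 10)
  expect_equal(one$merged$accession, direct$accession)
})

test_that("bundles tidy into long ranked tables and serialize to JSON", {
  idx <- toy_index()
  cvecs <- list(`1` = c(tt1 = 1, tt2 = 0.8), `2` = c(tt4 = 1))
  bundle <- recommend_midr(idx, cvecs, cluster_sizes = c(`1` = 2L, `2` = 1L),
                           top_k = 2)
  tab <- tidy(bundle)
  expect_true(all(c("merged", "cluster_1", "cluster_2") %in% tab$list))
  expect_true(all(tab$score >= 0 & tab$score <= 1))

  path <- tempfile(fileext = ".json")
  write_recommendations(bundle, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$mode, "midr")
  expect_equal(back$merged$accession, bundle$merged$accession)
  expect_true(file.exists(sub("\\.json$", ".tsv", path)))
})
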