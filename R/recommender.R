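#' Build a searchable dataset index
#'
#' Preprocesses each dataset's title + summary as one document, optionally
#' applies a word-group normalization map, embeds the documents in a fitted
#' TF-IDF space and stores the unit-normalized vectors next to the records.
#'
#' @param datasets Dataset tibble as from [read_datasets()].
#' @param model A `tfidf_model` (fit it on the union of dataset and
#'   publication texts; see [fit_tfidf()]).
#' @param word_groups Optional `word_group_map` applied to the tokens.
#' @param stopwords,lemmatizer Passed to [preprocess()].
#' @return A `dataset_index`: list with `records` (the tibble), `matrix`
#'   (terms x datasets `dgCMatrix`, unit columns) and `model`.
#' @export
build_index <- function(datasets, model, word_groups = NULL,
                        stopwords = default_stopwords(),
                        lemmatizer = lemmatize_en) {
  docs <- preprocess(paste(datasets$title, datasets$summary),
                     stopwords = stopwords, lemmatizer = lemmatizer)
  if (!is.null(word_groups)) docs <- apply_normalization(docs, word_groups)
  M <- vectorize_corpus(docs, model)
  colnames(M) <- datasets$accession
  structure(list(records = datasets, matrix = M, model = model),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d datasets over %d terms\n",
              nrow(x$records), nrow(x$matrix)))
  invisible(x)
}

#' Rank datasets against a query vector
#'
#' Scores every indexed dataset by cosine similarity to the query (both
#' sides unit-normalized TF-IDF, so all scores lie in [0, 1]) and returns
#' the top `top_k`, ties broken by accession ascending. A zero query vector
#' yields an empty result with a warning rather than an error, so batch runs
#' survive degenerate clusters.
#'
#' @param index A `dataset_index`.
#' @param query Named numeric vector (e.g. from [researcher_vector()]).
#' @param top_k Number of results (>= 1).
#' @return Tibble with columns `rank`, `accession`, `score`, `title`.
#' @export
rank_datasets <- function(index, query, top_k = 10L) {
  stopifnot(inherits(index, "dataset_index"))
  if (nrow(index$records) == 0L) abort("The dataset index is empty.")
  if (top_k < 1L) abort("top_k must be >= 1.")
  empty <- tibble(rank = integer(), accession = character(),
                  score = numeric(), title = character())
  if (is_zero_vec(query)) {
    warn("Zero query vector; returning no recommendations.")
    return(empty)
  }
  query <- unit_norm(query)
  q <- query[names(query) %in% rownames(index$matrix)]
  if (length(q) == 0L) {
    warn("Query shares no vocabulary with the index; returning no recommendations.")
    return(empty)
  }
  scores <- as.numeric(Matrix::crossprod(
    index$matrix[names(q), , drop = FALSE], q))
  ord <- order(-scores, index$records$accession)
  top <- head(ord, top_k)
  tibble(rank = seq_along(top),
         accession = index$records$accession[top],
         score = scores[top],
         title = index$records$title[top])
}

#' Baseline recommendation from a single researcher vector
#'
#' One ranked list from the whole-profile vector. With a strongly imbalanced
#' publication record this list reflects only the dominant research field —
#' the limitation the multi-interest modes address.
#'
#' @param index A `dataset_index`.
#' @param profile_vector Named numeric vector from [researcher_vector()].
#' @param top_k List length (default 10).
#' @return A `recommendation_bundle` with `mode = "baseline"`.
#' @export
recommend_baseline <- function(index, profile_vector, top_k = 10L) {
  ranked <- rank_datasets(index, profile_vector, top_k = top_k)
  ranked$source_cluster <- "baseline"
  new_bundle(mode = "baseline", merged = ranked,
             per_cluster = list(), suppressed = integer(0))
}

#' Multi-interest recommendation (merged round-robin list)
#'
#' Ranks datasets independently against each cluster vector, suppresses
#' clusters whose mean top-10 similarity is at or below `threshold` (such
#' clusters represent interests outside the scope of the indexed
#' repository), orders the surviving clusters by size descending (ties:
#' lower id first) and interleaves their lists round-robin — skipping
#' accessions already emitted — until `top_k` items or exhaustion.
#'
#' @param index A `dataset_index`.
#' @param cluster_vectors Named list of cluster vectors (names are cluster
#'   ids) from [cluster_vector()].
#' @param cluster_sizes Optional named integer vector of cluster sizes used
#'   for the round-robin order; defaults to equal sizes (id order).
#' @param top_k Per-cluster and merged list length (default 10).
#' @param threshold Suppression threshold on the mean top-10 similarity
#'   (default 0.05; suppression applies at exactly the threshold).
#' @return A `recommendation_bundle` with `mode = "midr"`: `per_cluster`
#'   ranked tibbles, the `merged` tibble and `suppressed_clusters`.
#' @export
recommend_midr <- function(index, cluster_vectors, cluster_sizes = NULL,
                           top_k = 10L, threshold = 0.05) {
  parts <- rank_clusters(index, cluster_vectors, cluster_sizes, top_k, threshold)
  merged <- round_robin(parts$per_cluster[parts$order], top_k)
  new_bundle(mode = "midr", merged = merged,
             per_cluster = parts$per_cluster, suppressed = parts$suppressed)
}

#' Multi-interest recommendation with per-cluster lists kept separate
#'
#' Same per-cluster ranking and suppression as [recommend_midr()], but the
#' lists are reported per research interest instead of merged.
#'
#' @inheritParams recommend_midr
#' @return A `recommendation_bundle` with `mode = "midr_separate"` and
#'   `merged = NULL`.
#' @export
recommend_midr_separate <- function(index, cluster_vectors, cluster_sizes = NULL,
                                    top_k = 10L, threshold = 0.05) {
  parts <- rank_clusters(index, cluster_vectors, cluster_sizes, top_k, threshold)
  new_bundle(mode = "midr_separate", merged = NULL,
             per_cluster = parts$per_cluster, suppressed = parts$suppressed)
}

rank_clusters <- function(index, cluster_vectors, cluster_sizes, top_k, threshold) {
  if (length(cluster_vectors) == 0L)
    abort("No eligible cluster vectors; fall back to recommend_baseline().")
  ids <- names(cluster_vectors) %||% as.character(seq_along(cluster_vectors))
  names(cluster_vectors) <- ids
  per_cluster <- list()
  suppressed <- character(0)
  for (id in ids) {
    ranked <- rank_datasets(index, cluster_vectors[[id]], top_k = top_k)
    if (!cluster_relevance_keep(head(ranked$score, 10L), threshold = threshold)) {
      suppressed <- c(suppressed, id)
      next
    }
    ranked$source_cluster <- id
    per_cluster[[id]] <- ranked
  }
  kept <- names(per_cluster)
  sizes <- if (is.null(cluster_sizes)) setNames(rep(1L, length(ids)), ids) else cluster_sizes
  ord <- kept[order(-as.integer(sizes[kept]), as_numeric_id(kept))]
  list(per_cluster = per_cluster, order = ord, suppressed = suppressed)
}

as_numeric_id <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (anyNA(num)) ids else num
}

# interleave ranked lists one row at a time, skipping already-emitted
# accessions, until top_k rows or exhaustion
round_robin <- function(lists, top_k) {
  out <- list()
  seen <- character(0)
  pos <- rep(1L, length(lists))
  emitted <- 0L
  repeat {
    advanced <- FALSE
    for (li in seq_along(lists)) {
      tab <- lists[[li]]
      while (pos[li] <= nrow(tab) && tab$accession[pos[li]] %in% seen)
        pos[li] <- pos[li] + 1L
      if (pos[li] <= nrow(tab)) {
        row <- tab[pos[li], ]
        pos[li] <- pos[li] + 1L
        seen <- c(seen, row$accession)
        out[[length(out) + 1L]] <- row
        emitted <- emitted + 1L
        advanced <- TRUE
        if (emitted >= top_k) break
      }
    }
    if (emitted >= top_k || !advanced) break
  }
  merged <- dplyr::bind_rows(out)
  if (nrow(merged)) merged$rank <- seq_len(nrow(merged))
  merged
}

#' Keep-or-suppress decision for one cluster's ranking
#'
#' A cluster is suppressed when the mean similarity of its top results (at
#' most 10) is less than or equal to `threshold` — the signature of a
#' research interest with no relevant datasets in the index. An empty list
#' is always suppressed.
#'
#' @param scores Numeric similarity scores of the cluster's top-ranked
#'   datasets (<= 10 values).
#' @param threshold Suppression threshold (default 0.05).
#' @return `TRUE` to keep, `FALSE` to suppress.
#' @export
cluster_relevance_keep <- function(scores, threshold = 0.05) {
  if (length(scores) == 0L) return(FALSE)
  mean(scores) > threshold
}

new_bundle <- function(mode, merged, per_cluster, suppressed) {
  structure(
    list(mode = mode, merged = merged, per_cluster = per_cluster,
         suppressed_clusters = suppressed),
    class = "recommendation_bundle"
  )
}

#' @export
print.recommendation_bundle <- function(x, ...) {
  cat(sprintf("<recommendation_bundle> mode %s: %d cluster list(s)%s%s\n",
              x$mode, length(x$per_cluster),
              if (!is.null(x$merged)) sprintf(", %d merged items", nrow(x$merged)) else "",
              if (length(x$suppressed_clusters))
                sprintf(", %d suppressed", length(x$suppressed_clusters)) else ""))
  invisible(x)
}

#' @rdname recommend_midr
#' @param x A `recommendation_bundle`.
#' @param ... Unused.
#' @export
tidy.recommendation_bundle <- function(x, ...) {
  rows <- list()
  if (!is.null(x$merged) && nrow(x$merged))
    rows$merged <- dplyr::mutate(x$merged, list = "merged")
  for (id in names(x$per_cluster))
    rows[[paste0("c", id)]] <- dplyr::mutate(x$per_cluster[[id]], list = paste0("cluster_", id))
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    dplyr::select(out, "list", "source_cluster", "rank", "accession",
                  "score", "title")
  } else {
    tibble(list = character(), source_cluster = character(), rank = integer(),
           accession = character(), score = numeric(), title = character())
  }
}

#' Write a recommendation bundle to JSON (with a TSV mirror)
#'
#' @param bundle A `recommendation_bundle`.
#' @param path Output `.json` path; a sibling `.tsv` with the tidy rows is
#'   written next to it.
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(bundle, path) {
  as_rows <- function(tab) {
    purrr::pmap(list(tab$rank, tab$accession, tab$score, tab$source_cluster),
                function(rank, accession, score, src)
                  list(rank = rank, accession = accession,
                       score = round(score, 6), source_cluster = src))
  }
  obj <- list(
    mode = bundle$mode,
    merged = if (is.null(bundle$merged)) NULL else as_rows(bundle$merged),
    per_cluster = purrr::map(bundle$per_cluster, as_rows),
    suppressed_clusters = as.list(bundle$suppressed_clusters)
  )
  write_atomic_json(obj, path)
  tidy_tab <- tidy(bundle)
  utils::write.table(tidy_tab, sub("\\.json$", ".tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
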