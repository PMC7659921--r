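#' Planted topic model for synthetic corpora
#'
#' Builds `n_topics` multinomials over a shared synthetic vocabulary
#' (`kw0001`, `kw0002`, ...): each topic concentrates mass `1 - overlap` on
#' its own block of terms (random within-block weights) and spreads the
#' remaining `overlap` mass uniformly over the whole vocabulary, so
#' `overlap = 0` gives disjoint supports and `overlap -> 1` near-identical
#' topics. This emulates the multi-interest structure the recommender
#' assumes — distinct research fields with a controllable amount of shared
#' vocabulary.
#'
#' @param n_topics Number of topics.
#' @param vocab_size Vocabulary size (at least `10 * n_topics`).
#' @param overlap Shared probability mass in [0, 1).
#' @param seed Integer RNG seed.
#' @return A `topic_model`: list with `prob` (topics x vocab matrix, rows
#'   sum to 1), `vocab`, `overlap`, `seed`.
#' @export
make_topics <- function(n_topics, vocab_size, overlap = 0.02, seed = 1L) {
  if (vocab_size < 10L * n_topics)
    abort("vocab_size must be at least 10 * n_topics.")
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1).")
  set.seed(seed)
  vocab <- sprintf("kw%04d", seq_len(vocab_size))
  block <- split(seq_len(vocab_size),
                 cut(seq_len(vocab_size), breaks = n_topics, labels = FALSE))
  prob <- matrix(overlap / vocab_size, nrow = n_topics, ncol = vocab_size,
                 dimnames = list(NULL, vocab))
  for (t in seq_len(n_topics)) {
    w <- stats::rexp(length(block[[t]])) + 0.2
    prob[t, block[[t]]] <- prob[t, block[[t]]] + (1 - overlap) * w / sum(w)
  }
  structure(list(prob = prob, vocab = vocab, n_topics = n_topics,
                 overlap = overlap, seed = seed),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> %d topics over %d terms (overlap %.2f)\n",
              x$n_topics, length(x$vocab), x$overlap))
  invisible(x)
}

draw_doc <- function(topics, topic, len) {
  sample(topics$vocab, len, replace = TRUE, prob = topics$prob[topic, ])
}

#' Generate a synthetic researcher with planted interests
#'
#' Draws each paper's tokens from the multinomial of its interest topic.
#' Documents are generated directly in token form (the post-preprocessing
#' representation), so generation does not depend on the lemmatizer; titles
#' and abstracts are assembled from the tokens for I/O round-trips. MeSH
#' terms are sampled from the topic's highest-probability terms (prefixed
#' `MH:`).
#'
#' @param topics A `topic_model`.
#' @param interests Integer topic ids (the researcher's research fields).
#' @param papers_per_topic Integer paper counts, parallel to `interests`.
#' @param year_range Length-2 integer vector; years drawn uniformly.
#' @param doc_length Tokens per paper.
#' @param seed Integer RNG seed.
#' @param name Researcher display name.
#' @return List with `profile` (a `researcher_profile` whose publication
#'   tibble carries a `tokens` list column) and `labels` (hidden topic per
#'   paper).
#' @export
make_researcher <- function(topics, interests, papers_per_topic,
                            year_range = c(2012L, 2019L), doc_length = 60L,
                            seed = 1L, name = "synthetic-researcher") {
  stopifnot(length(interests) == length(papers_per_topic))
  if (sum(papers_per_topic) < 1L) abort("A researcher needs at least one paper.")
  set.seed(seed)
  labels <- rep(interests, papers_per_topic)
  pubs <- purrr::map(seq_along(labels), function(i) {
    toks <- draw_doc(topics, labels[i], doc_length)
    top_terms <- names(sort(topics$prob[labels[i], ], decreasing = TRUE))[1:20]
    tibble(
      pmid = 100000L + i,
      title = paste(toks[1:min(6, length(toks))], collapse = " "),
      abstract = paste(toks[-(1:min(6, length(toks)))], collapse = " "),
      year = sample(seq(year_range[1], year_range[2]), 1L),
      mesh_terms = list(paste0("MH:", sample(top_terms, 5L))),
      tokens = list(toks)
    )
  })
  pubs <- dplyr::bind_rows(pubs)
  list(profile = new_researcher_profile(name, pubs), labels = labels)
}

#' Generate synthetic dataset metadata with hidden topic labels
#'
#' Each dataset's title + summary tokens are drawn from its topic's
#' multinomial; accessions are synthetic (`SYN000001`, ...). Per-topic
#' counts may be 0 to create dataset-free topics (interests with nothing to
#' recommend, exercising the suppression threshold).
#'
#' @param topics A `topic_model`.
#' @param n_per_topic Scalar, or an integer vector of per-topic dataset
#'   counts (0 allowed).
#' @param summary_length Tokens per dataset document.
#' @param seed Integer RNG seed.
#' @return List with `datasets` (tibble as from [read_datasets()], plus a
#'   `tokens` list column) and `labels` (named topic id per accession).
#' @export
make_datasets <- function(topics, n_per_topic = 30L, summary_length = 60L,
                          seed = 1L) {
  if (length(n_per_topic) == 1L)
    n_per_topic <- rep(n_per_topic, topics$n_topics)
  stopifnot(length(n_per_topic) == topics$n_topics, all(n_per_topic >= 0L))
  set.seed(seed)
  labels <- rep(seq_len(topics$n_topics), n_per_topic)
  recs <- purrr::map(seq_along(labels), function(i) {
    toks <- draw_doc(topics, labels[i], summary_length)
    tibble(
      accession = sprintf("SYN%06d", i),
      title = paste(toks[1:min(6, length(toks))], collapse = " "),
      summary = paste(toks[-(1:min(6, length(toks)))], collapse = " "),
      submission_date = as.Date("2015-01-01") + (i %% 1500L),
      pmids = list(integer(0)),
      tokens = list(toks)
    )
  })
  datasets <- dplyr::bind_rows(recs)
  list(datasets = datasets, labels = setNames(labels, datasets$accession))
}

#' Oracle star ratings from hidden topic labels
#'
#' Stands in for a human rater on synthetic worlds: a recommended dataset
#' earns 3 stars when its hidden topic equals the cluster's topic, 2 stars
#' for a designated adjacent topic, 1 star otherwise.
#'
#' @param recommendations Tibble with an `accession` column (a ranked list).
#' @param labels Named topic id per accession (from [make_datasets()]).
#' @param cluster_topic The topic the rated cluster represents.
#' @param adjacent Topic ids counted as partially relevant (default none).
#' @return Integer star vector aligned to the recommendation ranks.
#' @export
oracle_rate <- function(recommendations, labels, cluster_topic,
                        adjacent = integer(0)) {
  unknown <- setdiff(recommendations$accession, names(labels))
  if (length(unknown))
    abort(paste0("No hidden label for accession(s): ",
                 paste(unknown, collapse = ", ")))
  lab <- unname(labels[recommendations$accession])
  ifelse(lab == cluster_topic, 3L, ifelse(lab %in% adjacent, 2L, 1L))
}

#' Generate the default synthetic world
#'
#' The standard end-to-end fixture: 4 well-separated topics (overlap 0.02)
#' over a 400-term vocabulary; 30 datasets each for topics 1-3 and none for
#' topic 4; one researcher with interests in topics 1, 2 and 4 (10, 9 and 8
#' papers). Topic 4 is dataset-free by design, so its cluster must be
#' suppressed by the 0.05 relevance threshold. The whole pipeline on this
#' world runs in seconds.
#'
#' @param n_topics Number of topics.
#' @param vocab_size Vocabulary size.
#' @param overlap Topic overlap mass.
#' @param datasets_per_topic Per-topic dataset counts (recycled scalar
#'   allowed; the default leaves the last topic empty).
#' @param interests,papers_per_topic Researcher design.
#' @param doc_length Tokens per document.
#' @param seed Integer RNG seed (sub-seeds for topics, datasets and the
#'   researcher are derived from it).
#' @return A `synthetic_world`: list with `topics`, `datasets`,
#'   `dataset_labels`, `profile`, `paper_labels`, `seed`.
#' @export
simulate_world <- function(n_topics = 4L, vocab_size = 400L, overlap = 0.02,
                           datasets_per_topic = c(30L, 30L, 30L, 0L),
                           interests = c(1L, 2L, 4L),
                           papers_per_topic = c(10L, 9L, 8L),
                           doc_length = 60L, seed = 7L) {
  if (length(datasets_per_topic) == 1L)
    datasets_per_topic <- rep(datasets_per_topic, n_topics)
  topics <- make_topics(n_topics, vocab_size, overlap = overlap, seed = seed)
  ds <- make_datasets(topics, n_per_topic = datasets_per_topic,
                      summary_length = doc_length, seed = seed + 1L)
  res <- make_researcher(topics, interests = interests,
                         papers_per_topic = papers_per_topic,
                         doc_length = doc_length, seed = seed + 2L)
  structure(
    list(topics = topics, datasets = ds$datasets, dataset_labels = ds$labels,
         profile = res$profile, paper_labels = res$labels, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d topics, %d datasets, researcher with %d papers (seed %d)\n",
    x$topics$n_topics, nrow(x$datasets), x$profile$n_papers, x$seed))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Writes `datasets.jsonl`, `pubs.jsonl`, `profile.json` and `labels.json`
#' (hidden topic labels for datasets and papers) into `dir`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- world$datasets
  ds_lines <- purrr::pmap_chr(
    list(ds$accession, ds$title, ds$summary, as.character(ds$submission_date), ds$pmids),
    function(acc, title, summary, date, pmids)
      jsonlite::toJSON(list(accession = acc, title = title, summary = summary,
                            submission_date = date, pmids = as.list(pmids)),
                       auto_unbox = TRUE)
  )
  writeLines(ds_lines, file.path(dir, "datasets.jsonl"))
  pubs <- world$profile$publications
  pub_lines <- purrr::pmap_chr(
    list(pubs$pmid, pubs$title, pubs$abstract, pubs$year, pubs$mesh_terms),
    function(pmid, title, abstract, year, mesh)
      jsonlite::toJSON(list(pmid = pmid, title = title, abstract = abstract,
                            year = year, mesh_terms = as.list(mesh)),
                       auto_unbox = TRUE)
  )
  writeLines(pub_lines, file.path(dir, "pubs.jsonl"))
  write_profile(world$profile, file.path(dir, "profile.json"))
  write_atomic_json(
    list(dataset_labels = as.list(world$dataset_labels),
         paper_labels = as.list(world$paper_labels),
         interests = as.list(sort(unique(world$paper_labels))),
         seed = world$seed),
    file.path(dir, "labels.json"))
  invisible(dir)
}
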