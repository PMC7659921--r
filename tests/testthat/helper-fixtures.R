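# shared fixture builders; everything is generated in code at test time

write_jsonl <- function(objs, path = tempfile(fileext = ".jsonl")) {
  writeLines(vapply(objs, function(o) as.character(jsonlite::toJSON(o, auto_unbox = TRUE)),
                    character(1)), path)
  path
}

dataset_row <- function(accession = "GSE1", title = "a title",
                        summary = "a summary", submission_date = "2019-01-02",
                        pmids = list()) {
  list(accession = accession, title = title, summary = summary,
       submission_date = submission_date, pmids = pmids)
}

publication_row <- function(pmid = 1L, title = "a paper title",
                            abstract = "an abstract", year = 2018L,
                            mesh_terms = list()) {
  list(pmid = pmid, title = title, abstract = abstract, year = year,
       mesh_terms = mesh_terms)
}

# a word_embedding with hand-set vectors, to control neighbor structure
fake_embedding <- function(vectors, counts = NULL) {
  norms <- sqrt(rowSums(vectors^2))
  vectors <- vectors / norms
  counts <- counts %||% stats::setNames(rep(1L, nrow(vectors)), rownames(vectors))
  structure(list(vectors = vectors, counts = counts, dims = ncol(vectors),
                 window = 2L, min_count = 1L, seed = 1L),
            class = "word_embedding")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent brute-force tf-idf (smoothed log idf, unit norm) for tiny corpora
brute_tfidf_vector <- function(tokens, corpus, min_df = 1L, ngram_max = 2L) {
  grams <- function(tk) {
    out <- tk
    if (ngram_max >= 2 && length(tk) >= 2)
      out <- c(out, paste(tk[-length(tk)], tk[-1]))
    out
  }
  n <- length(corpus)
  all_terms <- sort(unique(unlist(lapply(corpus, grams))))
  df <- sapply(all_terms, function(w) sum(vapply(corpus, function(d) w %in% grams(d), logical(1))))
  vocab <- all_terms[df >= min_df]
  tf <- sapply(vocab, function(w) sum(grams(tokens) == w))
  idf <- log((1 + n) / (1 + df[vocab])) + 1
  w <- tf * idf
  w <- w[w > 0]
  if (length(w) == 0) return(stats::setNames(numeric(0), character(0)))
  w / sqrt(sum(w^2))
}

# independent cosine on named numeric vectors
brute_cosine <- function(x, y) {
  terms <- union(names(x), names(y))
  a <- stats::setNames(rep(0, length(terms)), terms); a[names(x)] <- x
  b <- stats::setNames(rep(0, length(terms)), terms); b[names(y)] <- y
  if (sum(a^2) == 0 || sum(b^2) == 0) return(0)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# all distinct permutations of a small integer vector (for the IDCG oracle)
unique_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_permutations(rest)) out[[length(out) + 1L]] <- c(v, p)
  }
  out
}

# brute-force ideal DCG: maximum DCG over every distinct ordering
brute_idcg <- function(g, k) {
  max(vapply(unique_permutations(g), function(p) {
    m <- min(k, length(p))
    sum(p[seq_len(m)] / log2(seq_len(m) + 1))
  }, numeric(1)))
}

# two-interest profile on a clean 2-topic world, used by recommender tests
imbalance_fixture <- function(n_a = 9L, n_b = 1L, seed = 101L) {
  tp <- make_topics(2L, vocab_size = 100L, overlap = 0, seed = seed)
  ds <- make_datasets(tp, n_per_topic = 15L, summary_length = 40L, seed = seed + 1L)
  rs <- make_researcher(tp, interests = c(1L, 2L), papers_per_topic = c(n_a, n_b),
                        doc_length = 40L, seed = seed + 2L)
  pubs <- rs$profile$publications
  model <- fit_tfidf(c(ds$datasets$tokens, pubs$tokens), min_df = 2L)
  index <- build_index(ds$datasets, model, lemmatizer = identity)
  paper_vecs <- lapply(pubs$tokens, vectorize, model = model)
  list(topics = tp, datasets = ds$datasets, dataset_labels = ds$labels,
       profile = rs$profile, paper_labels = rs$labels, model = model,
       index = index, paper_vecs = paper_vecs)
}
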