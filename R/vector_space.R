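#' Fit a TF-IDF vector space model
#'
#' Builds the shared vector space in which publications and datasets are
#' compared. The vocabulary contains all unigrams and (by default) bigrams
#' with document frequency at least `min_df`; higher n-gram orders are
#' excluded because they inflate sparsity. IDF is the smoothed logarithmic
#' variant `idf(w) = ln((1 + n_docs) / (1 + df(w))) + 1`. Fit the model on
#' the union of dataset and publication texts so researcher and dataset
#' vectors live in one comparable space.
#'
#' @param corpus List of token vectors, one per document.
#' @param min_df Minimum document frequency for a term to enter the
#'   vocabulary.
#' @param ngram_max Maximum n-gram size (1 or 2; default 2, i.e. unigrams
#'   and bigrams).
#' @return A `tfidf_model`: list with `vocabulary` (sorted character vector),
#'   `df` and `idf` (named numeric vectors), `min_df`, `ngram_max`,
#'   `n_docs_fit`.
#' @export
fit_tfidf <- function(corpus, min_df = 2L, ngram_max = 2L) {
  stopifnot(length(corpus) > 0L, ngram_max %in% c(1L, 2L))
  n_docs <- length(corpus)
  df <- count_vector(unlist(lapply(corpus, function(d) unique(ngrams(d, ngram_max))),
                            use.names = FALSE))
  keep <- df >= min_df
  if (!any(keep))
    abort(sprintf("Vocabulary is empty at min_df = %d; lower min_df.", min_df))
  vocab <- sort(names(df)[keep])
  df <- df[vocab]
  idf <- log((1 + n_docs) / (1 + df)) + 1
  structure(
    list(vocabulary = vocab, df = df, idf = idf, min_df = min_df,
         ngram_max = ngram_max, n_docs_fit = n_docs),
    class = "tfidf_model"
  )
}

# unigrams plus adjacent bigrams ("a b") of a token vector
ngrams <- function(tokens, ngram_max) {
  if (ngram_max >= 2L && length(tokens) >= 2L) {
    c(tokens, paste(tokens[-length(tokens)], tokens[-1]))
  } else {
    tokens
  }
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat(sprintf("<tfidf_model> %d terms (min_df %d, n-grams up to %d) fit on %d docs\n",
              length(x$vocabulary), x$min_df, x$ngram_max, x$n_docs_fit))
  invisible(x)
}

#' @rdname fit_tfidf
#' @param x A `tfidf_model`.
#' @param ... Unused.
#' @export
tidy.tfidf_model <- function(x, ...) {
  tibble(term = x$vocabulary, df = unname(x$df), idf = unname(x$idf))
}

#' @rdname fit_tfidf
#' @export
glance.tfidf_model <- function(x, ...) {
  tibble(n_terms = length(x$vocabulary), n_docs_fit = x$n_docs_fit,
         min_df = x$min_df, ngram_max = x$ngram_max)
}

#' Embed a document in a fitted TF-IDF space
#'
#' Weight of term `w` is `tf(w) * idf(w)`, unit-normalized. Out-of-vocabulary
#' terms are ignored; a document with no in-vocabulary terms yields the zero
#' vector (an empty named numeric vector), never an error.
#'
#' @param tokens Token vector of one document (for a dataset, the
#'   preprocessed title + summary; for a paper, title + abstract).
#' @param model A `tfidf_model`.
#' @return Named numeric vector (sparse term -> weight map) with unit
#'   Euclidean norm, or an empty vector for a fully out-of-vocabulary
#'   document.
#' @export
vectorize <- function(tokens, model) {
  stopifnot(inherits(model, "tfidf_model"))
  tf <- count_vector(ngrams(tokens, model$ngram_max))
  tf <- tf[names(tf) %in% model$vocabulary]
  if (length(tf) == 0L) return(setNames(numeric(0), character(0)))
  unit_norm(tf * model$idf[names(tf)])
}

#' Embed a corpus as a sparse term-by-document matrix
#'
#' @param corpus List of token vectors.
#' @param model A `tfidf_model`.
#' @return A `dgCMatrix` (terms x documents) whose non-zero columns are
#'   unit-normalized TF-IDF vectors over the model vocabulary.
#' @export
vectorize_corpus <- function(corpus, model) {
  vecs <- lapply(corpus, vectorize, model = model)
  ii <- unlist(lapply(vecs, function(v) match(names(v), model$vocabulary)))
  jj <- rep(seq_along(vecs), vapply(vecs, length, integer(1)))
  Matrix::sparseMatrix(
    i = ii %||% integer(0), j = jj, x = unlist(vecs, use.names = FALSE),
    dims = c(length(model$vocabulary), length(corpus)),
    dimnames = list(model$vocabulary, names(corpus))
  )
}

#' Recency weight of a publication
#'
#' Exponential decay `lambda = exp(-k * t)` with `t` the number of years
#' between the reference year and the publication year, so recent papers
#' dominate the researcher vector. The default decay rate is `k = 0.05`;
#' `k = 0` disables decay.
#'
#' @param pub_year Publication year(s).
#' @param k Decay rate per year (>= 0).
#' @param reference_year Year from which age is counted (e.g. the newest
#'   publication year of the profile, or the current year).
#' @return Numeric weight(s) in (0, 1].
#' @export
recency_weight <- function(pub_year, k = 0.05, reference_year) {
  stopifnot(k >= 0)
  if (any(pub_year > reference_year))
    abort("Publication year after the reference year.")
  exp(-k * (reference_year - pub_year))
}

#' Recency-weighted researcher (or cluster) vector
#'
#' Combines per-paper TF-IDF vectors into a single profile vector: each
#' paper vector is scaled by its recency weight, the sum is divided by the
#' number of papers, and (by default) the result is unit-normalized for
#' cosine ranking. [cluster_vector()] is the same construction restricted to
#' the papers of one cluster — the "pseudo-researcher" that represents one
#' research interest.
#'
#' @param vectors List of named numeric paper vectors (from [vectorize()]).
#' @param years Integer vector of publication years, parallel to `vectors`.
#' @param k Recency decay rate (default 0.05).
#' @param reference_year Defaults to `max(years)` for reproducibility; set
#'   to the wall-clock year to age a static profile.
#' @param normalize Unit-normalize the result (default `TRUE`; cosine
#'   ranking is scale-invariant, so this only stabilizes reported scores).
#' @return Named numeric vector; empty if every constituent vector is zero
#'   (flagged with a warning).
#' @export
researcher_vector <- function(vectors, years, k = 0.05,
                              reference_year = NULL, normalize = TRUE) {
  stopifnot(length(vectors) >= 1L, length(vectors) == length(years))
  reference_year <- reference_year %||% max(years)
  lambda <- recency_weight(years, k = k, reference_year = reference_year)
  acc <- unlist(purrr::map2(vectors, lambda, function(v, l) v * l))
  if (is.null(acc) || length(acc) == 0L) {
    warn("All constituent paper vectors are zero; returning a zero profile vector.")
    return(setNames(numeric(0), character(0)))
  }
  v <- tapply(acc, names(acc), sum) / length(vectors)
  v <- setNames(as.numeric(v), names(v))
  if (normalize) unit_norm(v) else v
}

#' @rdname researcher_vector
#' @export
cluster_vector <- researcher_vector

#' Save / load a TF-IDF model
#'
#' The model is stored as a JSON header (`min_df`, `ngram_max`,
#' `n_docs_fit`) next to a TSV vocabulary table (`term`, `df`, `idf`).
#'
#' @param model A `tfidf_model`.
#' @param dir Directory to hold `model.json` and `vocabulary.tsv`.
#' @return `write_tfidf()` returns `dir` invisibly; `read_tfidf()` a
#'   `tfidf_model`.
#' @export
write_tfidf <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_atomic_json(list(min_df = model$min_df, ngram_max = model$ngram_max,
                         n_docs_fit = model$n_docs_fit),
                    file.path(dir, "model.json"))
  utils::write.table(
    data.frame(term = model$vocabulary, df = unname(model$df),
               idf = unname(model$idf)),
    file.path(dir, "vocabulary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname write_tfidf
#' @export
read_tfidf <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  tab <- utils::read.delim(file.path(dir, "vocabulary.tsv"),
                           stringsAsFactors = FALSE)
  structure(
    list(vocabulary = tab$term,
         df = setNames(tab$df, tab$term),
         idf = setNames(tab$idf, tab$term),
         min_df = meta$min_df, ngram_max = meta$ngram_max,
         n_docs_fit = meta$n_docs_fit),
    class = "tfidf_model"
  )
}
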