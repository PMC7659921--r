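#' Train a distributional word embedding
#'
#' Builds dense word vectors from a tokenized corpus by factorising the
#' positive pointwise-mutual-information (PPMI) co-occurrence matrix with a
#' truncated SVD. Co-occurrence is counted within a symmetric window.
#' The construction is fully deterministic, so the `seed` argument is part of
#' the reproducibility contract but does not influence the result.
#'
#' @param corpus List of token vectors (one per document), e.g. from
#'   [preprocess()].
#' @param years Optional integer vector of per-document years, parallel to
#'   `corpus`.
#' @param min_year If given (with `years`), documents published before this
#'   year are dropped from the training corpus — e.g. 1998 to restrict a
#'   biomedical corpus to the microarray era.
#' @param dims Embedding dimensionality (capped at the vocabulary size).
#' @param window Symmetric co-occurrence window in tokens.
#' @param min_count Minimum corpus frequency for a term to enter the model.
#' @param seed Recorded on the model; the fit itself is deterministic.
#' @return A `word_embedding`: list with `vectors` (term-by-dims matrix with
#'   unit-normalized rows), `counts` (term corpus frequencies) and the call
#'   parameters.
#' @export
train_embedding <- function(corpus, years = NULL, min_year = NULL,
                            dims = 50L, window = 5L, min_count = 2L,
                            seed = 1L) {
  if (!is.null(min_year)) {
    stopifnot(!is.null(years), length(years) == length(corpus))
    corpus <- corpus[years >= min_year]
  }
  corpus <- corpus[vapply(corpus, length, integer(1)) > 0L]
  if (length(corpus) == 0L) abort("Training corpus is empty (after any year filter).")
  counts <- count_vector(unlist(corpus, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= min_count])
  if (length(vocab) < 2L)
    abort("Fewer than 2 terms meet min_count; cannot train an embedding.")
  idx <- setNames(seq_along(vocab), vocab)

  ii <- integer(0); jj <- integer(0)
  for (doc in corpus) {
    d <- idx[doc]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2L) next
    for (off in seq_len(min(window, n - 1L))) {
      a <- d[seq_len(n - off)]
      b <- d[seq_len(n - off) + off]
      ii <- c(ii, a, b)
      jj <- c(jj, b, a)
    }
  }
  if (length(ii) == 0L) abort("No co-occurrence pairs within the window; corpus too sparse.")
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(vocab), length(vocab)),
                            dimnames = list(vocab, vocab))
  X <- as.matrix(X)
  total <- sum(X)
  rs <- rowSums(X)
  expected <- outer(rs, rs) / total
  P <- log(pmax(X, .Machine$double.eps) / pmax(expected, .Machine$double.eps))
  P[X == 0] <- 0
  P[P < 0] <- 0
  k <- min(dims, ncol(P))
  sv <- svd(P, nu = k, nv = 0)
  vectors <- sv$u %*% diag(sqrt(sv$d[seq_len(k)]), nrow = k)
  rownames(vectors) <- vocab
  norms <- sqrt(rowSums(vectors^2))
  norms[norms == 0] <- 1
  vectors <- vectors / norms
  structure(
    list(vectors = vectors, counts = counts[vocab], dims = k,
         window = window, min_count = min_count, seed = seed),
    class = "word_embedding"
  )
}

#' @export
print.word_embedding <- function(x, ...) {
  cat(sprintf("<word_embedding> %d terms x %d dims (window %d)\n",
              nrow(x$vectors), x$dims, x$window))
  invisible(x)
}

#' Nearest neighbors of a term in embedding space
#'
#' @param model A `word_embedding`.
#' @param term Query term; must be in the model vocabulary.
#' @param n Number of neighbors.
#' @return Tibble with columns `term` and `similarity`, sorted by descending
#'   cosine similarity; the query term itself is never returned.
#' @export
most_similar <- function(model, term, n = 5L) {
  stopifnot(inherits(model, "word_embedding"))
  if (!term %in% rownames(model$vectors))
    abort(sprintf("Term '%s' is not in the embedding vocabulary.", term))
  sims <- drop(model$vectors %*% model$vectors[term, ])
  sims <- sims[names(sims) != term]
  ord <- order(-sims, names(sims))
  top <- head(ord, n)
  tibble(term = names(sims)[top], similarity = unname(sims[top]))
}

#' Group near-synonymous terms by embedding neighborhood
#'
#' Forms an undirected graph with an edge between `w` and `u` whenever `u`
#' is among the `top_n` nearest neighbors of `w` with similarity at or above
#' `sim_threshold` (and both are in `vocab`); the word groups are the
#' connected components, and each group's representative is its most
#' corpus-frequent member (ties broken lexicographically). Terms absent from
#' the embedding vocabulary stay as singleton groups. Replacing group members
#' by their representative (e.g. HIV-1 and AIDS variants by a single frequent
#' surface form) makes sparse texts comparable before clustering and
#' vectorization.
#'
#' @param model A `word_embedding`.
#' @param vocab Terms to group (character vector).
#' @param corpus_frequencies Named integer vector of corpus frequencies
#'   (defaults to the model's own counts); terms missing here count as 0.
#' @param top_n Neighborhood size per term.
#' @param sim_threshold Minimum cosine for an edge.
#' @return A `word_group_map`: list with `mapping` (named character vector,
#'   term -> representative; idempotent), `groups` (representative -> member
#'   vector) and `corpus_frequencies`.
#' @export
build_word_groups <- function(model, vocab, corpus_frequencies = model$counts,
                              top_n = 5L, sim_threshold = 0.70) {
  stopifnot(top_n >= 1L)
  vocab <- unique(vocab)
  in_model <- vocab[vocab %in% rownames(model$vectors)]
  edges <- purrr::map(in_model, function(w) {
    nb <- most_similar(model, w, n = top_n)
    nb <- nb[nb$similarity >= sim_threshold & nb$term %in% vocab, ]
    if (nrow(nb) == 0L) return(NULL)
    cbind(w, nb$term)
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) |>
    igraph::add_vertices(length(vocab), name = vocab)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  freq <- function(term) {
    f <- corpus_frequencies[term]
    f[is.na(f)] <- 0
    unname(f)
  }
  mapping <- character(length(vocab))
  names(mapping) <- vocab
  groups <- list()
  for (cid in unique(comp)) {
    members <- sort(names(comp)[comp == cid])
    rep_term <- members[order(-freq(members), members)][1]
    mapping[members] <- rep_term
    groups[[rep_term]] <- members
  }
  structure(
    list(mapping = mapping, groups = groups,
         corpus_frequencies = corpus_frequencies),
    class = "word_group_map"
  )
}

#' @export
print.word_group_map <- function(x, ...) {
  multi <- sum(vapply(x$groups, length, integer(1)) > 1L)
  cat(sprintf("<word_group_map> %d terms in %d groups (%d non-singleton)\n",
              length(x$mapping), length(x$groups), multi))
  invisible(x)
}

#' Apply a word-group normalization map to tokens
#'
#' Replaces each token by its group representative; tokens outside the map
#' pass through unchanged. Length-preserving and idempotent.
#'
#' @param tokens A character token vector, or a list of them.
#' @param map A `word_group_map` (or a bare named character mapping).
#' @return Same shape as `tokens`.
#' @export
apply_normalization <- function(tokens, map) {
  mapping <- if (inherits(map, "word_group_map")) map$mapping else map
  replace_one <- function(tk) {
    hit <- match(tk, names(mapping))
    out <- tk
    out[!is.na(hit)] <- mapping[hit[!is.na(hit)]]
    out
  }
  if (is.list(tokens)) lapply(tokens, replace_one) else replace_one(tokens)
}

#' Save / load word embeddings in the standard text vector format
#'
#' One line per term: the term followed by its coordinates, space-separated,
#' with a `n_terms n_dims` header line.
#'
#' @param model A `word_embedding`.
#' @param path File path.
#' @return `write_embedding()` returns `path` invisibly; `read_embedding()`
#'   a `word_embedding` (corpus counts are not part of the format and are
#'   restored as 1).
#' @export
write_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), ncol(model$vectors)), con)
  writeLines(paste(rownames(model$vectors),
                   apply(model$vectors, 1, function(r)
                     paste(sprintf("%.8g", r), collapse = " "))),
             con)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(header[2])))
  rownames(vectors) <- terms
  structure(
    list(vectors = vectors, counts = setNames(rep(1L, length(terms)), terms),
         dims = header[2], window = NA_integer_, min_count = NA_integer_,
         seed = NA_integer_),
    class = "word_embedding"
  )
}
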