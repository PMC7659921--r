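#' Propose the concentration parameter from the profile size
#'
#' `alpha = 10 / sqrt(N)` with `N` the researcher's number of papers: more
#' publications imply more research interests, and a smaller alpha lets the
#' mixture grow more clusters, while the square root keeps the value stable
#' for large profiles. Full precision is retained; round only for display.
#'
#' @param n_papers Number of papers (>= 1).
#' @return The proposed alpha.
#' @examples
#' propose_alpha(100) # 1
#' @export
propose_alpha <- function(n_papers) {
  if (any(n_papers < 1)) abort("n_papers must be >= 1.")
  10 / sqrt(n_papers)
}

#' Cluster documents with a Dirichlet-process multinomial mixture
#'
#' Collapsed Gibbs sampling over a Dirichlet-process mixture of multinomials
#' on bag-of-words counts. Each sweep removes every document in turn and
#' reassigns it with probability proportional to `m_z * L(d | z)` for an
#' existing cluster `z` with `m_z` members, and `gamma_new * L(d | empty)`
#' for a fresh cluster, where `L` is the collapsed Dirichlet-multinomial
#' predictive with per-word pseudo-count `alpha`. Larger `alpha` flattens
#' the word likelihood and merges clusters, so the number of clusters is
#' inversely related to `alpha`; `gamma_new` is the orthodox
#' Chinese-restaurant new-table weight and is exposed separately. All
#' documents start in a single cluster, and sampling stops after `n_iter`
#' sweeps or as soon as fewer than 2% of documents change cluster in a
#' sweep. Deterministic given `seed`.
#'
#' @param docs List of token vectors (normalized text), one per document.
#' @param alpha Word smoothing pseudo-count (> 0); see [propose_alpha()].
#' @param gamma_new New-cluster weight (default 1).
#' @param n_iter Maximum number of Gibbs sweeps (default 50).
#' @param seed Integer RNG seed.
#' @return A `cluster_set`: list with `assignments` (integer per document,
#'   ids contiguous from 1 in order of first appearance), `sizes`, `alpha`,
#'   `gamma_new`, `seed`, `n_iterations_run`, `method`.
#' @export
dpmm_cluster <- function(docs, alpha, gamma_new = 1, n_iter = 50L, seed = 1L) {
  stopifnot(length(docs) >= 1L)
  if (alpha <= 0) abort("alpha must be > 0.")
  n <- length(docs)
  if (n == 1L) {
    return(new_cluster_set(1L, alpha = alpha, gamma_new = gamma_new,
                           seed = seed, n_iterations_run = 0L, method = "dpmm"))
  }
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  V <- length(vocab)
  doc_idx <- lapply(docs, function(d) {
    cv <- count_vector(d)
    list(idx = match(names(cv), vocab), cnt = as.numeric(cv), len = sum(cv))
  })
  Vb <- V * alpha
  set.seed(seed)

  # sequential CRP seating as initialization: documents are seated one at a
  # time by the same collapsed predictive used in the sweeps, so clusters can
  # grow from the start (an all-in-one start rarely escapes merged topics)
  z <- integer(n)
  K <- 0L
  ckw <- matrix(0, nrow = V, ncol = 0L)   # cluster word counts
  ck <- numeric(0)                         # cluster token totals
  m <- integer(0)                          # cluster sizes
  for (i in seq_len(n)) {
    d <- doc_idx[[i]]
    ll_new <- sum(lgamma(d$cnt + alpha) - lgamma(alpha)) -
      (lgamma(d$len + Vb) - lgamma(Vb))
    if (K == 0L) {
      lp <- log(gamma_new) + ll_new
    } else {
      A <- ckw[d$idx, , drop = FALSE]
      ll <- colSums(lgamma(A + d$cnt + alpha) - lgamma(A + alpha)) -
        (lgamma(ck + d$len + Vb) - lgamma(ck + Vb))
      lp <- c(log(m) + ll, log(gamma_new) + ll_new)
    }
    p <- exp(lp - max(lp))
    pick <- findInterval(runif(1) * sum(p), cumsum(p), left.open = TRUE) + 1L
    if (pick > K + 1L) pick <- K + 1L
    if (pick == K + 1L) {
      K <- K + 1L
      ckw <- cbind(ckw, 0)
      ck <- c(ck, 0)
      m <- c(m, 0L)
    }
    z[i] <- pick
    ckw[d$idx, pick] <- ckw[d$idx, pick] + d$cnt
    ck[pick] <- ck[pick] + d$len
    m[pick] <- m[pick] + 1L
  }

  iterations <- 0L
  for (sweep in seq_len(n_iter)) {
    changed <- 0L
    for (i in seq_len(n)) {
      d <- doc_idx[[i]]
      zi <- z[i]
      ckw[d$idx, zi] <- ckw[d$idx, zi] - d$cnt
      ck[zi] <- ck[zi] - d$len
      m[zi] <- m[zi] - 1L
      if (m[zi] == 0L) {
        ckw <- ckw[, -zi, drop = FALSE]
        ck <- ck[-zi]
        m <- m[-zi]
        z[z > zi] <- z[z > zi] - 1L
        K <- K - 1L
        zi <- 0L
      }
      # log predictive likelihood for each existing cluster, vectorized
      A <- ckw[d$idx, , drop = FALSE]
      ll <- colSums(lgamma(A + d$cnt + alpha) - lgamma(A + alpha)) -
        (lgamma(ck + d$len + Vb) - lgamma(ck + Vb))
      ll_new <- sum(lgamma(d$cnt + alpha) - lgamma(alpha)) -
        (lgamma(d$len + Vb) - lgamma(Vb))
      lp <- c(log(m) + ll, log(gamma_new) + ll_new)
      p <- exp(lp - max(lp))
      pick <- findInterval(runif(1) * sum(p), cumsum(p),
                           left.open = TRUE) + 1L
      if (pick > K + 1L) pick <- K + 1L
      if (pick == K + 1L) {
        K <- K + 1L
        ckw <- cbind(ckw, 0)
        ck <- c(ck, 0)
        m <- c(m, 0L)
      }
      z[i] <- pick
      ckw[d$idx, pick] <- ckw[d$idx, pick] + d$cnt
      ck[pick] <- ck[pick] + d$len
      m[pick] <- m[pick] + 1L
      if (pick != zi) changed <- changed + 1L
    }
    iterations <- sweep
    if (changed / n < 0.02) break
  }
  # compact ids in order of first appearance
  relabel <- match(z, unique(z))
  new_cluster_set(relabel, alpha = alpha, gamma_new = gamma_new, seed = seed,
                  n_iterations_run = iterations, method = "dpmm")
}

new_cluster_set <- function(assignments, alpha = NA_real_, gamma_new = NA_real_,
                            seed = NA_integer_, n_iterations_run = NA_integer_,
                            method = "dpmm", eligible = NULL, fallback = FALSE) {
  assignments <- as.integer(assignments)
  sizes <- table(assignments)
  structure(
    list(assignments = assignments,
         sizes = setNames(as.integer(sizes), names(sizes)),
         alpha = alpha, gamma_new = gamma_new, seed = seed,
         n_iterations_run = n_iterations_run, method = method,
         eligible = eligible %||% sort(unique(assignments)),
         fallback = fallback),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %s: %d docs in %d clusters (sizes %s)%s\n",
              x$method, length(x$assignments), length(x$sizes),
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", "),
              if (x$fallback) " [fallback: no eligible cluster]" else ""))
  invisible(x)
}

#' @rdname dpmm_cluster
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @export
tidy.cluster_set <- function(x, ...) {
  tibble(document = seq_along(x$assignments),
         cluster = x$assignments,
         eligible = x$assignments %in% x$eligible)
}

#' @rdname dpmm_cluster
#' @export
glance.cluster_set <- function(x, ...) {
  s <- cluster_summary(x)
  tibble(n_documents = length(x$assignments), n_clusters = s$a,
         n_multi = s$b, n_singleton = s$c,
         n_eligible = length(x$eligible), alpha = x$alpha,
         n_iterations_run = x$n_iterations_run, method = x$method)
}

#' Drop single-paper clusters from the recommendation-eligible set
#'
#' Clusters holding exactly one paper are unreliable interest estimates and
#' are excluded from recommendation (the papers stay in the assignment for
#' diagnostics). If every cluster is a singleton the eligible set is empty
#' and the `fallback` flag is raised so callers revert to the single
#' baseline researcher vector.
#'
#' @param clusters A `cluster_set`.
#' @return The `cluster_set` with `eligible` restricted to clusters holding
#'   at least two papers, and `fallback` set accordingly.
#' @export
prune_singletons <- function(clusters) {
  keep <- as.integer(names(clusters$sizes)[clusters$sizes >= 2L])
  clusters$eligible <- sort(keep)
  clusters$fallback <- length(keep) == 0L
  if (clusters$fallback)
    warn("All clusters are singletons; falling back to the baseline researcher vector.")
  clusters
}

#' Cluster-count summary
#'
#' Counts `a` = total clusters, `b` = clusters with more than one paper and
#' `c` = single-paper clusters (`a = b + c`).
#'
#' @param clusters A `cluster_set`.
#' @return One-row tibble with columns `a`, `b`, `c`.
#' @export
cluster_summary <- function(clusters) {
  sizes <- clusters$sizes
  tibble(a = length(sizes),
         b = sum(sizes > 1L),
         c = sum(sizes == 1L))
}

#' K-Means clustering of paper vectors (comparison baseline)
#'
#' Standard k-means (via [stats::kmeans()]) on TF-IDF paper vectors, used as
#' the fixed-`k` baseline against the non-parametric mixture in
#' cohesion-metric comparisons.
#'
#' @param vectors List of named numeric paper vectors, or a numeric matrix
#'   with one row per document.
#' @param k Number of clusters (`k <=` number of documents).
#' @param seed Integer RNG seed.
#' @param nstart Random restarts (default 10).
#' @return A `cluster_set` (ids contiguous in order of first appearance).
#' @export
kmeans_cluster <- function(vectors, k, seed = 1L, nstart = 10L) {
  X <- if (is.matrix(vectors)) vectors else named_vectors_to_matrix(vectors)
  if (k > nrow(X)) abort("k exceeds the number of documents.")
  set.seed(seed)
  fit <- if (k == nrow(X)) {
    # the default algorithm requires k < n; seed every point as its own
    # center (a zero-inertia solution)
    kmeans(X, centers = X, algorithm = "Lloyd", iter.max = 100L)
  } else {
    kmeans(X, centers = k, nstart = nstart, iter.max = 100L)
  }
  relabel <- match(fit$cluster, unique(fit$cluster))
  new_cluster_set(relabel, seed = seed, method = "kmeans",
                  n_iterations_run = fit$iter)
}

# dense docs-by-terms matrix over the union vocabulary
named_vectors_to_matrix <- function(vectors) {
  vocab <- sort(unique(unlist(lapply(vectors, names))))
  X <- matrix(0, nrow = length(vectors), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    if (length(v)) X[i, names(v)] <- v
  }
  X
}
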