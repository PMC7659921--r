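#' Default run configuration
#'
#' All tunable parameters of the pipeline with their standard values:
#' recency decay `k_decay = 0.05`, TF-IDF `min_df = 2` and `ngram_max = 2`,
#' `alpha = "auto"` (the 10/sqrt(N) rule), `gamma_new = 1`, list length
#' `top_k = 10`, suppression `threshold = 0.05`, embedding neighborhood
#' `top_n_neighbors = 5` with `sim_threshold = 0.70`, and
#' `reference_year = "auto"` (newest publication year of the profile).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    k_decay = 0.05, min_df = 2L, ngram_max = 2L, alpha = "auto",
    gamma_new = 1.0, top_k = 10L, threshold = 0.05, top_n_neighbors = 5L,
    sim_threshold = 0.70, seed = 1L, reference_year = "auto", n_iter = 50L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read a flat key/value config file
#'
#' One `key = value` pair per line; `#` starts a comment; unquoted numbers
#' are coerced, `auto` is kept as a string. Keys must be known configuration
#' names; omitted keys take their defaults.
#'
#' @param path Config file path.
#' @return Named list as from [default_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(p) {
    v <- gsub('^"|"$', "", p[2])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(default_config, vals)
}

resolve_alpha <- function(config, n_papers) {
  if (identical(config$alpha, "auto")) propose_alpha(n_papers) else as.numeric(config$alpha)
}

resolve_reference_year <- function(config, years) {
  if (identical(config$reference_year, "auto")) max(years) else as.integer(config$reference_year)
}

log_config <- function(config, stage) {
  message(sprintf("[midr:%s] config: %s", stage,
                  paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                                              character(1)),
                        sep = "=", collapse = " ")))
}

profile_vectors <- function(profile, model, config) {
  pubs <- profile$publications
  docs <- preprocess(paste(pubs$title, pubs$abstract))
  vecs <- lapply(docs, vectorize, model = model)
  list(docs = docs, vecs = vecs,
       reference_year = resolve_reference_year(config, pubs$year))
}

require_artifact <- function(path, stage_hint) {
  if (!file.exists(path))
    abort(sprintf("Missing input artifact '%s'; run the '%s' stage first.",
                  path, stage_hint))
  path
}

#' Run one pipeline stage
#'
#' Staged command pipeline over the package functions, mirroring the CLI
#' subcommands. Every stage logs the resolved configuration and the seed,
#' writes its outputs atomically and fails with the name of the stage to run
#' first when an upstream artifact is missing.
#'
#' Stages and the `paths` entries they use:
#' * `simulate`: `out` (directory) — writes the default synthetic world.
#' * `index`: `datasets`, optional `publications`, `out` (directory) —
#'   fits TF-IDF on the union corpus and writes the model + index.
#' * `profile`: `cv`, `candidates`, `out` — CV title matching.
#' * `stats`: `datasets` — prints link statistics.
#' * `cluster`: `profile`, `out` — DPMM clustering with the alpha rule.
#' * `recommend`: `index`, `profile`, `mode`, `out`, and `clusters` for the
#'   multi-interest modes.
#' * `evaluate`: `recs`, `ratings`, `out` — NDCG@k / P@k report.
#'
#' @param config Configuration list (see [default_config()]).
#' @param subcommand Stage name.
#' @param paths Named list of input/output paths (and `mode` for
#'   `recommend`).
#' @return The stage's main artifact path (or result tibble for `stats`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config(), subcommand, paths = list()) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "index", "profile", "stats",
                            "cluster", "recommend", "evaluate"))
  log_config(config, subcommand)
  switch(subcommand,
         simulate = stage_simulate(config, paths),
         index = stage_index(config, paths),
         profile = stage_profile(config, paths),
         stats = stage_stats(config, paths),
         cluster = stage_cluster(config, paths),
         recommend = stage_recommend(config, paths),
         evaluate = stage_evaluate(config, paths))
}

stage_simulate <- function(config, paths) {
  world <- simulate_world(seed = as.integer(config$seed))
  write_world(world, paths$out)
  invisible(paths$out)
}

stage_index <- function(config, paths) {
  datasets <- read_datasets(require_artifact(paths$datasets, "simulate"))
  ds_docs <- preprocess(paste(datasets$title, datasets$summary))
  union_docs <- ds_docs
  if (!is.null(paths$publications) && file.exists(paths$publications)) {
    pubs <- read_publications(paths$publications)
    union_docs <- c(union_docs, preprocess(paste(pubs$title, pubs$abstract)))
  }
  model <- fit_tfidf(union_docs, min_df = as.integer(config$min_df),
                     ngram_max = as.integer(config$ngram_max))
  dir.create(paths$out, showWarnings = FALSE, recursive = TRUE)
  write_tfidf(model, file.path(paths$out, "model"))
  file.copy(paths$datasets, file.path(paths$out, "datasets.jsonl"),
            overwrite = TRUE)
  invisible(paths$out)
}

read_index_dir <- function(index_dir) {
  model <- read_tfidf(require_artifact(file.path(index_dir, "model"), "index"))
  datasets <- read_datasets(file.path(index_dir, "datasets.jsonl"))
  build_index(datasets, model)
}

stage_profile <- function(config, paths) {
  cv_text <- readLines(require_artifact(paths$cv, "profile inputs"), warn = FALSE)
  candidates <- read_publications(require_artifact(paths$candidates, "profile inputs"))
  profile <- match_publications(candidates, cv_text)
  write_profile(profile, paths$out)
  invisible(paths$out)
}

stage_stats <- function(config, paths) {
  datasets <- read_datasets(require_artifact(paths$datasets, "simulate"))
  stats <- link_stats(datasets)
  message(sprintf(
    "[midr:stats] datasets %d | with articles %d | links %d (mean %.2f, max %d, unique %d)",
    stats$n_datasets, stats$n_with_articles, stats$total_links,
    stats$mean_links, stats$max_links, stats$n_unique_pmids))
  invisible(stats)
}

stage_cluster <- function(config, paths) {
  profile <- read_profile(require_artifact(paths$profile, "profile"))
  pubs <- profile$publications
  docs <- preprocess(paste(pubs$title, pubs$abstract))
  alpha <- resolve_alpha(config, profile$n_papers)
  cs <- dpmm_cluster(docs, alpha = alpha,
                     gamma_new = as.numeric(config$gamma_new),
                     n_iter = as.integer(config$n_iter),
                     seed = as.integer(config$seed))
  cs <- prune_singletons(cs)
  s <- cluster_summary(cs)
  write_atomic_json(
    list(assignments = as.list(cs$assignments),
         sizes = as.list(setNames(as.integer(cs$sizes), names(cs$sizes))),
         alpha = alpha, gamma_new = as.numeric(config$gamma_new),
         seed = as.integer(config$seed),
         eligible = as.list(cs$eligible), fallback = cs$fallback,
         summary = list(a = s$a, b = s$b, c = s$c)),
    paths$out)
  invisible(paths$out)
}

stage_recommend <- function(config, paths) {
  mode <- match.arg(paths$mode %||% "baseline",
                    c("baseline", "midr", "separate"))
  index <- read_index_dir(require_artifact(paths$index, "index"))
  profile <- read_profile(require_artifact(paths$profile, "profile"))
  pv <- profile_vectors(profile, index$model, config)
  if (mode == "baseline") {
    v <- researcher_vector(pv$vecs, profile$publications$year,
                           k = config$k_decay,
                           reference_year = pv$reference_year)
    bundle <- recommend_baseline(index, v, top_k = as.integer(config$top_k))
  } else {
    if (is.null(paths$clusters) || !file.exists(paths$clusters))
      abort("Multi-interest recommendation needs a clusters file; run the 'cluster' stage first.")
    cl <- jsonlite::fromJSON(paths$clusters)
    assignments <- as.integer(unlist(cl$assignments))
    eligible <- as.integer(unlist(cl$eligible))
    if (length(eligible) == 0L) {
      warn("No eligible cluster; falling back to the baseline recommendation.")
      v <- researcher_vector(pv$vecs, profile$publications$year,
                             k = config$k_decay,
                             reference_year = pv$reference_year)
      bundle <- recommend_baseline(index, v, top_k = as.integer(config$top_k))
    } else {
      years <- profile$publications$year
      cvecs <- lapply(eligible, function(id) {
        sel <- assignments == id
        cluster_vector(pv$vecs[sel], years[sel], k = config$k_decay,
                       reference_year = pv$reference_year)
      })
      names(cvecs) <- eligible
      sizes <- setNames(vapply(eligible, function(id) sum(assignments == id),
                               integer(1)), eligible)
      bundle <- if (mode == "midr") {
        recommend_midr(index, cvecs, cluster_sizes = sizes,
                       top_k = as.integer(config$top_k),
                       threshold = config$threshold)
      } else {
        recommend_midr_separate(index, cvecs, cluster_sizes = sizes,
                                top_k = as.integer(config$top_k),
                                threshold = config$threshold)
      }
    }
  }
  write_recommendations(bundle, paths$out)
  invisible(paths$out)
}

stage_evaluate <- function(config, paths) {
  recs <- jsonlite::fromJSON(require_artifact(paths$recs, "recommend"),
                             simplifyVector = FALSE)
  ratings <- jsonlite::fromJSON(require_artifact(paths$ratings, "ratings input"),
                                simplifyVector = FALSE)
  k <- as.integer(config$top_k)
  per_cluster <- dplyr::bind_rows(lapply(ratings$clusters, function(cl) {
    dplyr::mutate(metric_report(as.integer(unlist(cl$stars)), k = k),
                  cluster_id = cl$cluster_id, .before = 1)
  }))
  overall <- average_separate(per_cluster)
  write_atomic_json(
    list(researcher = ratings$researcher %||% "unknown",
         mode = recs$mode,
         k = k,
         per_cluster = purrr::pmap(per_cluster, function(cluster_id, ndcg_at_k,
                                                          p_at_k_partial, p_at_k_strict)
           list(cluster_id = cluster_id, ndcg_at_k = ndcg_at_k,
                p_at_k_partial = p_at_k_partial, p_at_k_strict = p_at_k_strict)),
         average = as.list(overall)),
    paths$out)
  invisible(paths$out)
}
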