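#' Read dataset metadata records
#'
#' Reads a collection of dataset metadata records (one per GEO-style series:
#' accession, title, summary, submission date and linked article PMIDs) from
#' JSON Lines or TSV. Malformed rows are reported with their line number;
#' duplicate PMIDs within one record are collapsed with a warning.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line) or `"tsv"` (header row
#'   with the same field names; `pmids` as a `;`-separated list, possibly
#'   empty).
#' @return A tibble with columns `accession`, `title`, `summary`,
#'   `submission_date` (`Date`) and `pmids` (list column of integer vectors).
#' @export
read_datasets <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "jsonl") {
    rows <- read_jsonl(path)
    if (length(rows) == 0L) {
      warn("Empty dataset file; returning zero records.")
      return(empty_datasets())
    }
    recs <- purrr::imap(rows, function(row, i) {
      for (f in c("accession", "title", "summary", "submission_date")) {
        if (is.null(row[[f]]) || !nzchar(as.character(row[[f]])[1]))
          abort(sprintf("Line %d: missing required field '%s'.", i, f))
      }
      pmids <- parse_pmids(row$pmids, i)
      tibble(
        accession = as.character(row$accession),
        title = as.character(row$title),
        summary = as.character(row$summary),
        submission_date = as.Date(row$submission_date),
        pmids = list(pmids)
      )
    })
    out <- dplyr::bind_rows(recs)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(tab) == 0L) {
      warn("Empty dataset file; returning zero records.")
      return(empty_datasets())
    }
    need <- c("accession", "title", "summary", "submission_date", "pmids")
    missing_cols <- setdiff(need, names(tab))
    if (length(missing_cols))
      abort(paste0("TSV is missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    for (i in seq_len(nrow(tab))) {
      for (f in c("accession", "title", "summary", "submission_date")) {
        if (is.na(tab[[f]][i]) || !nzchar(tab[[f]][i]))
          abort(sprintf("Line %d: missing required field '%s'.", i + 1L, f))
      }
    }
    pmids <- purrr::imap(tab$pmids, function(x, i) {
      if (is.na(x) || !nzchar(x)) return(integer(0))
      parse_pmids(strsplit(x, ";", fixed = TRUE)[[1]], i + 1L)
    })
    out <- tibble(
      accession = tab$accession, title = tab$title, summary = tab$summary,
      submission_date = as.Date(tab$submission_date), pmids = pmids
    )
  }
  if (anyDuplicated(out$accession))
    abort(paste0("Duplicate accession(s): ",
                 paste(unique(out$accession[duplicated(out$accession)]), collapse = ", ")))
  out
}

empty_datasets <- function() {
  tibble(accession = character(), title = character(), summary = character(),
         submission_date = as.Date(character()), pmids = list())
}

parse_pmids <- function(x, line) {
  if (is.null(x) || length(x) == 0L) return(integer(0))
  x <- suppressWarnings(as.integer(unlist(x)))
  if (anyNA(x)) abort(sprintf("Line %d: non-integer PMID.", line))
  if (anyDuplicated(x)) {
    warn(sprintf("Line %d: duplicate PMIDs collapsed.", line))
    x <- unique(x)
  }
  x
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

#' Read publication records
#'
#' Reads PubMed-style publication records (PMID, title, abstract, publication
#' year, MeSH terms) from JSON Lines, in file order.
#'
#' @param path Path to a JSONL file, one publication object per line.
#' @param reference_year Upper bound accepted for `year` (defaults to the
#'   current calendar year).
#' @return A tibble with columns `pmid` (integer, `NA` allowed), `title`,
#'   `abstract`, `year` (integer) and `mesh_terms` (list column of character
#'   vectors).
#' @export
read_publications <- function(path, reference_year = as.integer(format(Sys.Date(), "%Y"))) {
  stopifnot(file.exists(path))
  rows <- read_jsonl(path)
  if (length(rows) == 0L) {
    warn("Empty publication file; returning zero records.")
    return(empty_publications())
  }
  recs <- purrr::imap(rows, function(row, i) {
    if (is.null(row$title) || !nzchar(as.character(row$title)[1]))
      abort(sprintf("Line %d: missing required field 'title'.", i))
    year <- suppressWarnings(as.integer(row$year))
    if (is.null(row$year) || is.na(year))
      abort(sprintf("Line %d: 'year' is not an integer.", i))
    if (year < 1900L || year > reference_year)
      abort(sprintf("Line %d: year %d outside [1900, %d].", i, year, reference_year))
    pmid <- if (is.null(row$pmid)) NA_integer_ else suppressWarnings(as.integer(row$pmid))
    tibble(
      pmid = pmid,
      title = as.character(row$title),
      abstract = as.character(row$abstract %||% ""),
      year = year,
      mesh_terms = list(as.character(unlist(row$mesh_terms)))
    )
  })
  dplyr::bind_rows(recs)
}

empty_publications <- function() {
  tibble(pmid = integer(), title = character(), abstract = character(),
         year = integer(), mesh_terms = list())
}

#' Canonicalize a title for string matching
#'
#' Lower-cases, replaces every character that is not a letter or digit by a
#' space, collapses runs of whitespace and trims. Unicode letters are kept
#' (and lower-cased); symbols and punctuation map to space. Idempotent.
#'
#' @param title Character vector of titles.
#' @return Character vector of canonical forms (empty input stays empty).
#' @examples
#' normalize_title("HIV-1 Dynamics: A Review.")
#' @export
normalize_title <- function(title) {
  x <- tolower(title)
  x <- gsub("[^\\p{L}\\p{N}]+", " ", x, perl = TRUE)
  stringr::str_squish(x)
}

#' Resolve a researcher's publications against a CV
#'
#' Keeps exactly those candidate publications whose canonical title occurs as
#' a substring of the canonical CV text. Matching is exact on normalized
#' titles: a single-character typo in the CV rejects the publication (the
#' accepted failure mode of plain string matching). Candidates sharing one
#' normalized title collapse to the record with the lowest PMID.
#'
#' @param candidates Publication tibble as from [read_publications()]
#'   (typically a PubMed name-search result, which may contain homonymous
#'   authors' papers — the CV match is what disambiguates).
#' @param cv_text The researcher's CV or publication list as plain text.
#' @param name Researcher display name stored on the profile.
#' @param max_typo_distance Optional edit-distance tolerance per title
#'   (default 0 = exact matching only).
#' @return A `researcher_profile`: list with `name`, `publications` (tibble)
#'   and `n_papers`.
#' @export
match_publications <- function(candidates, cv_text, name = "researcher",
                               max_typo_distance = 0L) {
  stopifnot(is.character(cv_text), length(cv_text) >= 1L)
  cv_norm <- normalize_title(paste(cv_text, collapse = " "))
  if (!nzchar(cv_norm)) abort("CV text is empty after normalization.")
  norm <- normalize_title(candidates$title)
  hit <- nzchar(norm) & stringr::str_detect(cv_norm, stringr::fixed(norm))
  if (max_typo_distance > 0L && any(!hit)) {
    cv_words <- strsplit(cv_norm, " ", fixed = TRUE)[[1]]
    for (i in which(!hit)) {
      tw <- strsplit(norm[i], " ", fixed = TRUE)[[1]]
      # sliding window of equal word length; total edit distance over the window
      nw <- length(tw)
      if (nw == 0L || nw > length(cv_words)) next
      for (s in seq_len(length(cv_words) - nw + 1L)) {
        window <- paste(cv_words[s:(s + nw - 1L)], collapse = " ")
        if (utils::adist(window, norm[i]) <= max_typo_distance) {
          hit[i] <- TRUE
          break
        }
      }
    }
  }
  matched <- candidates[hit, , drop = FALSE]
  if (nrow(matched) == 0L)
    abort("No candidate title matched the CV; check that the CV lists publication titles verbatim.")
  matched$.norm <- normalize_title(matched$title)
  matched <- matched |>
    dplyr::group_by(.data$.norm) |>
    dplyr::slice_min(order_by = .data$pmid, n = 1L, with_ties = FALSE, na_rm = FALSE) |>
    dplyr::ungroup()
  # restore candidate order after the duplicate collapse
  matched <- matched[order(match(matched$.norm, normalize_title(candidates$title))), ]
  matched$.norm <- NULL
  new_researcher_profile(name, matched)
}

new_researcher_profile <- function(name, publications) {
  structure(
    list(name = name, publications = publications, n_papers = nrow(publications)),
    class = "researcher_profile"
  )
}

#' @export
print.researcher_profile <- function(x, ...) {
  cat(sprintf("<researcher_profile> %s: %d publication(s), years %s-%s\n",
              x$name, x$n_papers,
              min(x$publications$year), max(x$publications$year)))
  invisible(x)
}

#' @rdname match_publications
#' @param x A `researcher_profile`.
#' @param ... Unused.
#' @export
tidy.researcher_profile <- function(x, ...) x$publications

#' Write / read a researcher profile as JSON
#'
#' @param profile A `researcher_profile`.
#' @param path Output (input) path.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `researcher_profile`.
#' @export
write_profile <- function(profile, path) {
  pubs <- profile$publications
  obj <- list(
    name = profile$name,
    publications = purrr::pmap(
      list(pubs$pmid, pubs$title, pubs$abstract, pubs$year, pubs$mesh_terms),
      function(pmid, title, abstract, year, mesh) {
        list(pmid = if (is.na(pmid)) NULL else pmid, title = title,
             abstract = abstract, year = year, mesh_terms = as.list(mesh))
      })
  )
  write_atomic_json(obj, path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pubs <- dplyr::bind_rows(lapply(obj$publications, function(p) {
    tibble(pmid = as.integer(p$pmid %||% NA_integer_),
           title = p$title, abstract = p$abstract %||% "",
           year = as.integer(p$year),
           mesh_terms = list(as.character(unlist(p$mesh_terms))))
  }))
  new_researcher_profile(obj$name, pubs)
}

#' Corpus link statistics
#'
#' Summarizes dataset-to-article links across a collection: how many records
#' carry at least one linked article, the total and per-record mean number of
#' links, the largest link count on a single record and the number of
#' distinct PMIDs.
#'
#' @param datasets Dataset tibble as from [read_datasets()].
#' @return One-row tibble: `n_datasets`, `n_with_articles`, `total_links`,
#'   `mean_links` (`total_links / n_datasets`, 0 for an empty collection),
#'   `max_links`, `n_unique_pmids`.
#' @export
link_stats <- function(datasets) {
  n_links <- vapply(datasets$pmids, length, integer(1))
  n <- nrow(datasets)
  total <- sum(n_links)
  tibble(
    n_datasets = n,
    n_with_articles = sum(n_links > 0L),
    total_links = total,
    mean_links = if (n == 0L) 0 else total / n,
    max_links = if (n == 0L) 0L else max(n_links),
    n_unique_pmids = length(unique(unlist(datasets$pmids)))
  )
}
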