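#' Default English stopword list
#'
#' The standard snowball-style English stopword list shipped with the package
#' (`inst/extdata/stopwords_en.txt`), user-overridable in every function that
#' takes a `stopwords` argument.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "midr")
  readLines(path, warn = FALSE)
}

#' Dictionary/rule English lemmatizer
#'
#' Maps tokens to root forms: a small irregular-noun dictionary plus
#' conservative plural-stripping rules (`studies` -> `study`,
#' `classes` -> `class`, `cells` -> `cell`; `-ss`, `-us`, `-is` endings and
#' listed invariants such as `species` are left alone). Deliberately
#' noun-oriented and deterministic; any `function(tokens) tokens'` can be
#' plugged into [preprocess()] in its place.
#'
#' @param tokens Character vector of lower-cased tokens.
#' @return Character vector of the same length.
#' @export
lemmatize_en <- function(tokens) {
  irregular <- c(
    mice = "mouse", children = "child", men = "man", women = "woman",
    feet = "foot", teeth = "tooth", people = "person", genera = "genus"
  )
  invariant <- c("species", "series", "analysis", "diabetes", "rabies",
                 "measles", "aids")
  out <- tokens
  irr <- out %in% names(irregular)
  out[irr] <- irregular[out[irr]]
  todo <- !irr & !(out %in% invariant)
  n <- nchar(out)
  rule <- function(pattern, repl, min_n) {
    idx <- todo & n >= min_n & grepl(pattern, out)
    out[idx] <<- sub(pattern, repl, out[idx])
    todo[idx] <<- FALSE
  }
  rule("ies$", "y", 5L)          # studies -> study
  rule("(ss|ch|sh|x|z)es$", "\\1", 5L)  # classes -> class, boxes -> box
  rule("uses$", "us", 6L)        # viruses -> virus
  # -ss / -us / -is endings are singular; otherwise strip a final s
  keep <- todo & grepl("(ss|us|is)$", out)
  todo[keep] <- FALSE
  rule("s$", "", 3L)             # cells -> cell
  out
}

#' Preprocess free text into tokens
#'
#' Applies the cleaning chain used for both publication and dataset texts:
#' URLs removed, lower-casing, punctuation and symbols replaced by spaces,
#' stopwords dropped, "junk" tokens dropped (shorter than 2 characters or
#' purely numeric), and each surviving token lemmatized to its root form.
#'
#' @param text Character vector; each element is one document.
#' @param stopwords Stopword list (default [default_stopwords()]).
#' @param lemmatizer Function mapping a token vector to root forms
#'   (default [lemmatize_en()]); pass `identity` to disable.
#' @return A list of character token vectors, one per input document (order
#'   and multiplicity preserved within each document).
#' @examples
#' preprocess("HIV-infected cells cells")[[1]]
#' @export
preprocess <- function(text, stopwords = default_stopwords(),
                       lemmatizer = lemmatize_en) {
  lapply(text, function(doc) {
    if (is.na(doc) || !nzchar(trimws(doc))) return(character(0))
    doc <- gsub("(https?://|www\\.)\\S+", " ", doc, perl = TRUE)
    doc <- tolower(doc)
    doc <- gsub("[^\\p{L}\\p{N}]+", " ", doc, perl = TRUE)
    toks <- strsplit(stringr::str_squish(doc), " ", fixed = TRUE)[[1]]
    toks <- toks[nchar(toks) >= 2L]
    toks <- toks[!grepl("^\\p{N}+$", toks, perl = TRUE)]
    toks <- toks[!(toks %in% stopwords)]
    if (length(toks)) lemmatizer(toks) else character(0)
  })
}
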