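# shared internal helpers

# cosine between two sparse term->weight maps (named numeric vectors)
cosine_named <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) return(0)
  shared <- intersect(names(x), names(y))
  if (length(shared) == 0L) return(0)
  num <- sum(x[shared] * y[shared])
  den <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  if (den == 0) 0 else num / den
}

# unit-normalize a named numeric vector; zero vectors pass through untouched
unit_norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) x else x / n
}

is_zero_vec <- function(x) length(x) == 0L || all(x == 0)

# term-count vector (multiplicity preserved) from a character vector
count_vector <- function(tokens) {
  if (length(tokens) == 0L) return(setNames(numeric(0), character(0)))
  tab <- table(tokens)
  setNames(as.numeric(tab), names(tab))
}

# atomic JSON write: temp file in the target directory, then rename
write_atomic_json <- function(obj, path, digits = 10) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = digits,
                       pretty = TRUE, null = "null")
  file.rename(tmp, path)
  invisible(path)
}
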