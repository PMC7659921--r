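test_that("preprocess strips URLs, stopwords, junk and lemmatizes", {
  toks <- preprocess("Genes were expressed; see http://x.y/path?q=1")[[1]]
  expect_false(any(grepl("http|x\\.y", toks)))
  expect_false("were" %in% toks)
  expect_true(all(c("gene", "expressed") %in% toks))

  expect_equal(preprocess("")[[1]], character(0))
  expect_equal(preprocess("   ")[[1]], character(0))

  # order and multiplicity preserved
  expect_equal(preprocess("HIV-infected cells cells")[[1]],
               c("hiv", "infected", "cell", "cell"))
})

test_that("preprocess drops short and purely numeric tokens", {
  toks <- preprocess("p53 x 2019 42 ab a")[[1]]
  expect_true("p53" %in% toks)   # alphanumeric mixes survive
  expect_true("ab" %in% toks)
  expect_false(any(c("x", "a", "2019", "42") %in% toks))
})

test_that("preprocess output never contains an active stopword", {
  sw <- default_stopwords()
  docs <- c("The quick brown fox was here", "We present results of our study",
            "It is what it is", "these those that this")
  for (toks in preprocess(docs, stopwords = sw))
    expect_length(intersect(toks, sw), 0)
})

test_that("the default lemmatizer maps plurals to roots", {
  expect_equal(lemmatize_en(c("cells", "studies", "classes", "viruses",
                              "mice", "species", "analysis", "virus")),
               c("cell", "study", "class", "virus",
                 "mouse", "species", "analysis", "virus"))
  # pluggable: identity lemmatizer leaves tokens untouched
  expect_equal(preprocess("cells", lemmatizer = identity)[[1]], "cells")
})

test_that("train_embedding is deterministic and honors the year filter", {
  corpus <- rep(list(c("gene", "expression", "tumor", "cell"),
                     c("gene", "tumor", "assay", "cell")), 6)
  m1 <- train_embedding(corpus, dims = 5, seed = 1)
  m2 <- train_embedding(corpus, dims = 5, seed = 1)
  expect_identical(m1$vectors, m2$vectors)

  # a pre-cutoff document's private term disappears from the vocabulary
  corpus2 <- c(corpus, list(rep(c("microfiche", "archive"), 3)))
  years <- c(rep(2005L, length(corpus)), 1997L)
  m3 <- train_embedding(corpus2, years = years, min_year = 1998L,
                        dims = 5, min_count = 2)
  expect_false("microfiche" %in% rownames(m3$vectors))
  expect_error(train_embedding(corpus2, years = years, min_year = 2050L),
               "empty")
})

test_that("repeated co-occurrence makes terms mutual near neighbors", {
  corpus <- c(rep(list(c("hiv", "aids", "therapy")), 10),
              rep(list(c("mouse", "genome", "assay")), 10))
  m <- train_embedding(corpus, dims = 4, min_count = 1)
  nb <- most_similar(m, "hiv", n = 2)
  expect_setequal(nb$term, c("aids", "therapy"))
  expect_true(all(nb$similarity > 0))
  # and the relation is mutual within the co-occurring group
  expect_true("hiv" %in% most_similar(m, "aids", n = 2)$term)
  # no co-occurrence, no similarity
  expect_lt(most_similar(m, "mouse", n = 5)$similarity[
    most_similar(m, "mouse", n = 5)$term == "hiv"], 1e-8)
})

test_that("most_similar excludes the query and sorts descending", {
  vecs <- rbind(a = c(1, 0), b = c(0.9, 0.1), c = c(0, 1))
  m <- fake_embedding(vecs)
  nb <- most_similar(m, "a", n = 2)
  expect_false("a" %in% nb$term)
  expect_equal(nb$term[1], "b")
  expect_true(all(diff(nb$similarity) <= 0))
  expect_error(most_similar(m, "zzz"), "not in the embedding")
})

test_that("word groups are connected components with frequency representatives", {
  # hiv ~ hiv1 ~ aids mutually similar; unrelated term far away
  vecs <- rbind(hiv = c(1, 0, 0), hiv1 = c(0.98, 0.2, 0), aids = c(0.95, 0.3, 0),
                mouse = c(0, 0, 1))
  freq <- c(hiv = 50L, hiv1 = 10L, aids = 20L, mouse = 5L)
  map <- build_word_groups(fake_embedding(vecs, freq), rownames(vecs),
                           corpus_frequencies = freq, sim_threshold = 0.7)
  expect_equal(unname(map$mapping[c("hiv", "hiv1", "aids")]),
               rep("hiv", 3))
  expect_equal(unname(map$mapping["mouse"]), "mouse")

  # an impossible threshold leaves every term a singleton
  id_map <- build_word_groups(fake_embedding(vecs, freq), rownames(vecs),
                              corpus_frequencies = freq, sim_threshold = 1.01)
  expect_equal(id_map$mapping, setNames(rownames(vecs), rownames(vecs)))
})

test_that("a similarity chain merges into one component", {
  # a-b and b-c above threshold; a-c below: still one group
  vecs <- rbind(a = c(1, 0), b = c(cos(pi / 5), sin(pi / 5)),
                c = c(cos(2 * pi / 5), sin(2 * pi / 5)))
  freq <- c(a = 3L, b = 2L, c = 1L)
  emb <- fake_embedding(vecs, freq)
  expect_lt(sum(emb$vectors["a", ] * emb$vectors["c", ]), 0.75)
  map <- build_word_groups(emb, c("a", "b", "c"), corpus_frequencies = freq,
                           sim_threshold = 0.75)
  expect_equal(unname(map$mapping), rep("a", 3))
})

test_that("word-group partitions cover the vocabulary and maps are idempotent", {
  corpus <- rep(list(c("gene", "genes", "tumor", "cancer", "assay")), 8)
  m <- train_embedding(corpus, dims = 4, min_count = 1)
  vocab <- rownames(m$vectors)
  map <- build_word_groups(m, vocab, top_n = 2, sim_threshold = 0.8)
  expect_setequal(unlist(map$groups), vocab)
  expect_equal(sum(lengths(map$groups)), length(vocab))  # disjoint
  expect_equal(unname(map$mapping[unname(map$mapping)]), unname(map$mapping))

  # a term absent from the embedding stays a singleton
  map2 <- build_word_groups(m, c(vocab, "unseen"), top_n = 2)
  expect_equal(unname(map2$mapping["unseen"]), "unseen")
})

test_that("apply_normalization is length-preserving and idempotent", {
  mapping <- c(hiv = "hiv", hiv1 = "hiv", aids = "hiv")
  expect_equal(apply_normalization(c("hiv1", "aids"), mapping), c("hiv", "hiv"))
  expect_equal(apply_normalization(c("x", "y"), character(0)), c("x", "y"))
  toks <- list(c("hiv1", "mouse", "aids"), character(0))
  once <- apply_normalization(toks, mapping)
  expect_equal(lengths(once), lengths(toks))
  expect_equal(apply_normalization(once, mapping), once)
})

test_that("embeddings survive the text-format round trip", {
  corpus <- rep(list(c("gene", "tumor", "assay", "cell")), 6)
  m <- train_embedding(corpus, dims = 3, min_count = 1)
  path <- tempfile(fileext = ".vec")
  write_embedding(m, path)
  back <- read_embedding(path)
  expect_equal(rownames(back$vectors), rownames(m$vectors))
  expect_equal(back$vectors, m$vectors, tolerance = 1e-6, ignore_attr = TRUE)
})
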