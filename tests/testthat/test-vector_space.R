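test_that("fit_tfidf enumerates unigram and bigram vocabulary under min_df", {
  corpus <- list(c("a", "b"), c("a", "c"))
  m1 <- fit_tfidf(corpus, min_df = 1)
  expect_setequal(m1$vocabulary, c("a", "b", "c", "a b", "a c"))
  m2 <- fit_tfidf(corpus, min_df = 2)
  expect_equal(m2$vocabulary, "a")
  expect_error(fit_tfidf(corpus, min_df = 3), "min_df")

  # a term present in every document attains the minimum idf
  m3 <- fit_tfidf(list(c("a", "b"), c("a", "c"), c("a", "d")), min_df = 1)
  expect_equal(unname(which.min(m3$idf[m3$vocabulary])),
               match("a", m3$vocabulary))
  expect_equal(glance(m1)$n_docs_fit, 2L)
  expect_equal(nrow(tidy(m1)), length(m1$vocabulary))
})

test_that("vectorize matches the closed-form tf-idf on a tiny corpus", {
  corpus <- list(c("a", "b"), c("a", "c"))
  m <- fit_tfidf(corpus, min_df = 1)
  v <- vectorize(c("a", "b"), m)
  expected <- brute_tfidf_vector(c("a", "b"), corpus, min_df = 1)
  expect_equal(v[order(names(v))], expected[order(names(expected))],
               tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)

  expect_length(vectorize(character(0), m), 0)
  expect_length(vectorize(c("zzz", "qqq"), m), 0)  # fully out-of-vocabulary

  # identical document implies cosine 1 with its fitted vector
  expect_equal(brute_cosine(vectorize(corpus[[1]], m), vectorize(corpus[[1]], m)),
               1, tolerance = 1e-9)
})

test_that("vectorize agrees with brute force on random small corpora", {
  set.seed(42)
  letters_pool <- c("a", "b", "c", "d", "e", "f", "g")
  for (rep in 1:5) {
    corpus <- lapply(1:6, function(i) sample(letters_pool, sample(3:8, 1), replace = TRUE))
    m <- fit_tfidf(corpus, min_df = 1)
    for (d in corpus[1:3]) {
      mine <- vectorize(d, m)
      ref <- brute_tfidf_vector(d, corpus, min_df = 1)
      expect_equal(mine[order(names(mine))], ref[order(names(ref))],
                   tolerance = 1e-10)
    }
  }
})

test_that("vectorize_corpus stacks unit columns aligned with the records", {
  corpus <- list(c("a", "b"), c("a", "c"), c("zzz"))
  m <- fit_tfidf(corpus[1:2], min_df = 1)
  M <- vectorize_corpus(corpus, m)
  expect_equal(dim(M), c(length(m$vocabulary), 3L))
  expect_equal(Matrix::colSums(M^2)[1:2], c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sum(M[, 3]), 0)  # out-of-vocabulary doc is a zero column
})

test_that("recency weights follow exponential decay", {
  expect_equal(recency_weight(2020, k = 0.05, reference_year = 2020), 1)
  expect_equal(recency_weight(2010, k = 0.05, reference_year = 2020),
               exp(-0.5), tolerance = 1e-12)
  expect_equal(recency_weight(1990, k = 0, reference_year = 2020), 1)
  expect_error(recency_weight(2021, k = 0.05, reference_year = 2020), "after")
})

test_that("researcher_vector combines recency-scaled paper vectors", {
  e1 <- c(x = 1); e2 <- c(y = 1)
  # two orthogonal unit papers, 10 years apart: coefficients lambda / N
  raw <- researcher_vector(list(e1, e2), years = c(2020, 2010),
                           reference_year = 2020, normalize = FALSE)
  expect_equal(unname(raw["x"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(raw["y"]), exp(-0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(raw["y"]), 0.30327, tolerance = 1e-4)

  # single paper: direction preserved
  single <- researcher_vector(list(c(x = 0.6, y = 0.8)), years = 2018)
  expect_equal(brute_cosine(single, c(x = 0.6, y = 0.8)), 1, tolerance = 1e-9)

  # two identical papers in different years stay parallel to the paper
  twin <- researcher_vector(list(e1, e1), years = c(2015, 2019))
  expect_equal(brute_cosine(twin, e1), 1, tolerance = 1e-9)

  # paper order does not matter
  a <- researcher_vector(list(e1, e2, c(x = 1, y = 1) / sqrt(2)),
                         years = c(2015, 2017, 2019))
  b <- researcher_vector(list(c(x = 1, y = 1) / sqrt(2), e2, e1),
                         years = c(2019, 2017, 2015))
  expect_equal(a[order(names(a))], b[order(names(b))], tolerance = 1e-12)

  expect_warning(z <- researcher_vector(list(setNames(numeric(0), character(0))),
                                        years = 2019), "zero")
  expect_length(z, 0)
})

test_that("an older year gives a paper's terms weakly smaller weight", {
  e1 <- c(x = 1); e2 <- c(y = 1)
  newer <- researcher_vector(list(e1, e2), years = c(2019, 2019),
                             reference_year = 2019, normalize = FALSE)
  older <- researcher_vector(list(e1, e2), years = c(2019, 2009),
                             reference_year = 2019, normalize = FALSE)
  expect_lt(older["y"], newer["y"])
  expect_equal(older["x"], newer["x"])
})

test_that("cluster_vector is researcher_vector restricted to a cluster", {
  vecs <- list(c(x = 1), c(y = 1), c(x = 1, y = 1) / sqrt(2))
  years <- c(2015, 2017, 2019)
  expect_equal(cluster_vector(vecs, years), researcher_vector(vecs, years))
  # cluster of one paper keeps the paper's direction
  one <- cluster_vector(vecs[2], years[2])
  expect_equal(brute_cosine(one, vecs[[2]]), 1, tolerance = 1e-9)

  # 3-paper cluster against a hand-summed oracle
  lambda <- exp(-0.05 * (2019 - years))
  acc <- c(x = 0, y = 0)
  for (i in 1:3) for (nm in names(vecs[[i]]))
    acc[nm] <- acc[nm] + lambda[i] * vecs[[i]][nm]
  byhand <- acc / 3
  mine <- cluster_vector(vecs, years, normalize = FALSE)
  expect_equal(mine[order(names(mine))], byhand[order(names(byhand))],
               tolerance = 1e-12)
})

test_that("tf-idf models survive the save/load round trip", {
  corpus <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  m <- fit_tfidf(corpus, min_df = 1)
  dir <- tempfile()
  write_tfidf(m, dir)
  back <- read_tfidf(dir)
  expect_equal(back$vocabulary, m$vocabulary)
  expect_equal(back$idf, m$idf, tolerance = 1e-12)
  expect_equal(vectorize(c("a", "b"), back), vectorize(c("a", "b"), m),
               tolerance = 1e-9)
})
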