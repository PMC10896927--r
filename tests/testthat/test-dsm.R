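test_that("HAL reproduces the worked toy vector (5, 0, 3)", {
  docs <- c(rep("target word1", 5), rep("target word3", 3), "word2 filler")
  hal <- build_hal(as_corpus(docs), window = 1)
  vec <- hal$vectors["target", c("word1", "word2", "word3")]
  expect_equal(unname(vec), c(5, 0, 3))
})

test_that("HAL counts adjacencies symmetrically", {
  hal <- build_hal(as_corpus("a b a b"), window = 1)
  expect_equal(hal$vectors["a", "b"], 3)
  expect_equal(hal$vectors["b", "a"], 3)
  # window saturation: all pairs in the document are counted
  doc <- "x y z x"
  sat <- build_hal(as_corpus(doc), window = 10)
  expect_equal(sat$vectors, hal_brute_force(as_corpus(doc), 10))
})

test_that("HAL equals brute-force pair enumeration on random small corpora", {
  set.seed(42)
  for (i in 1:12) {
    n_tok <- sample(5:50, 1)
    n_docs <- sample(1:3, 1)
    words <- letters[1:6]
    docs <- vapply(seq_len(n_docs), function(d)
      paste(sample(words, ceiling(n_tok / n_docs), replace = TRUE),
            collapse = " "), character(1))
    w <- sample(1:4, 1)
    expect_equal(build_hal(as_corpus(docs), window = w)$vectors,
                 hal_brute_force(as_corpus(docs), w))
  }
})

test_that("distance weighting applies the linear ramp", {
  hal <- build_hal(as_corpus("a x b"), window = 2, distance_weighting = TRUE)
  expect_equal(hal$vectors["a", "x"], 2)  # distance 1 -> weight 2
  expect_equal(hal$vectors["a", "b"], 1)  # distance 2 -> weight 1
})

test_that("LSA at full rank preserves raw-count cosines", {
  spec <- corpus_spec(n_documents = 12, doc_length = 20, seed = 3)
  corp <- generate_corpus(spec)
  m <- term_document_matrix(corp)
  lsa <- build_lsa(corp, n_dimensions = min(dim(m)))
  idx <- sample(rownames(m), 6)
  for (i in 1:5) {
    raw <- cosine_sim(m[idx[i], ], m[idx[i + 1], ])
    red <- cosine_sim(lsa$vectors[idx[i], ], lsa$vectors[idx[i + 1], ])
    expect_lt(abs(raw - red), 1e-10)
  }
})

test_that("proportional document profiles give cosine 1 at any dimensionality", {
  docs <- c("a a b", "a a a a b b", "c")  # rank-2 count matrix
  for (k in 1:2) {
    lsa <- build_lsa(as_corpus(docs), n_dimensions = k)
    expect_equal(cosine_sim(lsa$vectors["a", ], lsa$vectors["b", ]), 1,
                 tolerance = 1e-12)
  }
})

test_that("singular values match a hand-solved decomposition", {
  # term-document counts: a = (2,0,0), b = (0,1,0), c = (0,0,3)
  docs <- c("a a", "b", "c c c")
  lsa <- build_lsa(as_corpus(docs), n_dimensions = 3)
  expect_equal(lsa$singular_values, c(3, 2, 1))
  expect_error(build_lsa(as_corpus(docs), n_dimensions = 4), "exceeds")
  expect_error(build_lsa(as_corpus(docs), n_dimensions = 0), "positive")
  # rank-deficient matrix: duplicate documents
  dup <- c("a b", "a b", "c")
  expect_error(build_lsa(as_corpus(dup), n_dimensions = 3), "rank")
})

test_that("LSA truncation error decreases monotonically in rank", {
  spec <- corpus_spec(n_documents = 15, doc_length = 25, seed = 8)
  corp <- generate_corpus(spec)
  m <- term_document_matrix(corp)
  s <- svd(m)
  err <- vapply(1:6, function(k) {
    approx <- s$u[, 1:k, drop = FALSE] %*% diag(s$d[1:k], k) %*%
      t(s$v[, 1:k, drop = FALSE])
    sqrt(sum((m - approx)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("cosine similarity follows its defining identities", {
  expect_equal(cosine_sim(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(1, 1), c(1, 0)), sqrt(2) / 2)
  expect_error(cosine_sim(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_sim(c(1, 0), c(1, 0, 0)), "equal length")
  set.seed(2)
  for (i in 1:10) {
    u <- rnorm(5); v <- rnorm(5); alpha <- runif(1, 0.1, 10)
    expect_equal(cosine_sim(u, v), cosine_sim(v, u))
    expect_equal(cosine_sim(alpha * u, v), cosine_sim(u, v))
    expect_lte(abs(cosine_sim(u, v)), 1 + 1e-12)
  }
})

test_that("category ANOVA detects the designed association pattern", {
  spec <- corpus_spec(n_documents = 150, doc_length = 40,
                      association_strength = 0.8, direction = "both", seed = 4)
  corp <- generate_corpus(spec)
  for (space in list(build_lsa(corp, n_dimensions = 20), build_hal(corp, window = 2))) {
    an <- category_anova(cosine_table(space, spec$vocabulary))
    cm <- an$cell_means
    expect_gt(cm["past", "negative"], cm["past", "positive"])
    expect_gt(cm["future", "positive"], cm["future", "negative"])
    expect_lt(an$table$p[an$table$effect == "time_valence"], 0.05)
  }
})

test_that("constant cosines give zero F throughout", {
  tab <- expand.grid(time_word = c("p1", "f1"), valence_word = c("n1", "v1"),
                     stringsAsFactors = FALSE)
  tab$time_category <- ifelse(tab$time_word == "p1", "past", "future")
  tab$valence_category <- ifelse(tab$valence_word == "n1", "negative", "positive")
  tab$cosine <- 0.5
  class(tab) <- c("cosine_table", "data.frame")
  an <- category_anova(tab)
  expect_true(all(an$table$F == 0))
  expect_error(category_anova(tab[tab$time_category == "past", ]), "empty")
})
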