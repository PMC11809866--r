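test_that("tf-idf vocabulary enumerates all 1-3-grams", {
  f <- tfidf_featurize("a b c")
  expect_setequal(f$vocabulary, c("a", "b", "c", "a b", "b c", "a b c"))
})

test_that("tf-idf uses the smoothed log idf and L2-normalized rows", {
  docs <- c("x x y", "z", "w")
  f <- tfidf_featurize(docs, ngram_range = c(1, 1))
  n <- length(docs)
  # term x: tf 2, df 1 -> weight prop. to 2 * (ln(4/2) + 1)
  idf_x <- log((1 + n) / (1 + 1)) + 1
  expect_equal(f$idf[match("x", f$vocabulary)], idf_x)
  w_x <- 2 * idf_x
  w_y <- 1 * (log((1 + n) / (1 + 1)) + 1)
  row1 <- as.numeric(f$x[1, ])
  expect_equal(row1[match("x", f$vocabulary)],
               w_x / sqrt(w_x^2 + w_y^2))
  norms <- sqrt(Matrix::rowSums(f$x^2))
  expect_equal(as.numeric(norms), rep(1, 3))

  # a term present in every document gets the minimal idf ln(1) + 1 = 1
  f2 <- tfidf_featurize(c("t", "t u", "t v"), ngram_range = c(1, 1))
  expect_equal(f2$idf[match("t", f2$vocabulary)], 1)
})

test_that("empty documents produce zero rows, not errors", {
  f <- tfidf_featurize(c("a b", ""))
  expect_equal(sum(f$x[2, ]), 0)
})

test_that("projection onto a fitted vocabulary ignores unseen n-grams", {
  fit <- tfidf_featurize(c("a b", "b c"))
  proj <- tfidf_featurize("a zz", fit$ngram_range, fit$vocabulary, fit$idf)
  expect_equal(proj$vocabulary, fit$vocabulary)
  expect_gt(proj$x[1, match("a", fit$vocabulary)], 0)
})

test_that("lexicon features are hit counts over token counts", {
  lx <- lexicon_set(list(g = list(
    ed = c("fasting", "calorias"),
    other = c("guitar")
  )))
  x <- lexicon_featurize(
    c("today fasting again fasting one two three four five six", ""), lx
  )
  expect_equal(dim(x), c(2, 2))
  expect_equal(unname(x[1, 1]), 2 / 10)
  expect_equal(as.numeric(x[2, ]), c(0, 0))
})

test_that("the shipped demo lexicon set yields exactly 84 features", {
  lx <- demo_lexicons()
  expect_equal(length(lx$feature_names), 84L)
  sizes <- vapply(lx$groups, length, 0L)
  expect_equal(unname(sizes), c(24L, 29L, 12L, 10L, 9L))
  x <- lexicon_featurize("me siento sola y llorando por las calorias", lx)
  expect_equal(ncol(x), 84L)
  expect_gt(sum(x), 0)
})

test_that("SMOTE balances classes by interpolation between minority neighbours", {
  set.seed(3)
  x <- rbind(matrix(rnorm(10, mean = 0), 5),
             matrix(rnorm(40, mean = 5), 20))
  y <- rep(c("min", "maj"), c(5, 20))
  os <- smote_oversample(x, y, seed = 9)
  expect_equal(sum(os$y == "min"), 20)
  expect_equal(nrow(os$x), 40)  # 25 originals + 15 synthetic
  # originals untouched
  expect_equal(os$x[1:25, ], x)
  # synthetic points lie on segments between minority points (convexity):
  # every coordinate within the minority bounding box, and each synthetic
  # point is a convex combination of some minority pair
  synth <- os$x[26:40, , drop = FALSE]
  xm <- x[1:5, ]
  for (i in seq_len(nrow(synth))) {
    expect_true(all(synth[i, ] >= apply(xm, 2, min) - 1e-12))
    expect_true(all(synth[i, ] <= apply(xm, 2, max) + 1e-12))
    on_segment <- FALSE
    for (a in 1:5) for (b in 1:5) {
      if (a == b) next
      d <- xm[b, ] - xm[a, ]
      lam <- sum((synth[i, ] - xm[a, ]) * d) / sum(d^2)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((xm[a, ] + lam * d - synth[i, ])^2)) < 1e-9) {
        on_segment <- TRUE
      }
    }
    expect_true(on_segment)
  }
  # balanced input unchanged
  xb <- matrix(rnorm(8), 4); yb <- rep(c("a", "b"), 2)
  expect_equal(smote_oversample(xb, yb, seed = 1)$x, xb)
  # singleton minority
  expect_error(smote_oversample(x[1:21, ], rep(c("m", "M"), c(1, 20))),
               "duplicate")
})

test_that("SMOTE is deterministic under a fixed seed", {
  x <- matrix(rnorm(60), 30); y <- rep(c("a", "b"), c(10, 20))
  expect_identical(smote_oversample(x, y, seed = 4),
                   smote_oversample(x, y, seed = 4))
})

test_that("screeners recover a separable planted vocabulary", {
  corpus <- planted_corpus(n_pos = 20, n_neg = 30, d = 1, seed = 11)
  for (clf in c("logistic", "random_forest")) {
    m <- train_screener(corpus, "pos", featurizer = "tfidf",
                        classifier = clf, seed = 5)
    expect_gte(m$metrics$test$f1, 0.9)
  }
})

test_that("shuffled labels score near the majority-class rate", {
  set.seed(21)
  corpus <- planted_corpus(n_pos = 25, n_neg = 35, d = 1, seed = 12)
  corpus$label <- sample(corpus$label)
  m <- train_screener(corpus, "pos", seed = 6)
  maj <- max(table(corpus$label)) / nrow(corpus)
  expect_lt(abs(m$metrics$test$accuracy - maj), 0.25)
})

test_that("training is deterministic and rejects degenerate corpora", {
  corpus <- planted_corpus(seed = 13)
  m1 <- train_screener(corpus, "pos", seed = 7)
  m2 <- train_screener(corpus, "pos", seed = 7)
  expect_identical(m1$metrics, m2$metrics)
  one_class <- corpus[corpus$label == "pos", ]
  expect_error(train_screener(one_class, "pos"), "two classes")
  expect_error(train_screener(corpus, "nope"), "not present")
})

test_that("an svm screener trains on lexicon features", {
  corpus <- tibble::tibble(
    id = sprintf("u%02d", 1:30),
    text = c(replicate(15, paste(rep("llorando sola triste vacia", 4), collapse = " ")),
             replicate(15, paste(rep("guitar festival concert album", 4), collapse = " "))),
    label = rep(c("sad", "music"), each = 15)
  )
  m <- train_screener(corpus, "sad", featurizer = "lexicon",
                      classifier = "svm", seed = 2)
  expect_gte(m$metrics$test$f1, 0.9)
  expect_equal(nrow(glance(m)), 1)
  expect_true(all(c("split", "metric", "value") %in% names(tidy(m))))
})

test_that("harmlessness scores follow the planted vocabulary", {
  corpus <- planted_corpus(n_pos = 25, n_neg = 25, d = 1, seed = 14)
  m <- train_screener(corpus, "pos", seed = 8)
  p_pos <- score_texts(m, paste(rep("p01 p05 p09", 10), collapse = " "))
  p_neg <- score_texts(m, paste(rep("q01 q05 q09", 10), collapse = " "))
  expect_gt(p_pos, 0.5)
  expect_lt(p_neg, 0.5)
  expect_true(all(score_texts(m, corpus$text) >= 0))
  expect_true(all(score_texts(m, corpus$text) <= 1))
  expect_error(score_texts(list(), "x"), "fitted")

  acc <- tibble::tibble(id = "a", texts = list("p01 p02 p03"))
  expect_gt(harmlessness_score(m, acc), 0.5)
})

test_that("cohort selection keeps accounts above the certainty cut, ordered", {
  corpus <- planted_corpus(n_pos = 25, n_neg = 25, d = 1, seed = 15)
  m <- train_screener(corpus, "pos", seed = 9)
  acc <- tibble::tibble(
    id = c("b", "a", "z"),
    texts = list("p01 p02 p03 p04 p05", "p05 p06 p07 p01 p02",
                 "q01 q02 q03 q04 q05")
  )
  cohort <- select_contemplation_cohort(m, acc, threshold = 0.5)
  expect_true(all(cohort$id %in% c("a", "b")))
  expect_true(all(diff(cohort$probability) <= 0))
  none <- select_contemplation_cohort(m, acc, threshold = 1)
  expect_equal(nrow(none), 0)
})
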