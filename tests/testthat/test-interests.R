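tiny_vocab <- function() {
  topic_vocabulary(
    list(calories = "nutrition", diet = "nutrition", gym = "fitness",
         guitar = "music"),
    topics = c("nutrition", "fitness", "music")
  )
}

acct <- function(id, texts = character(0), liked = character(0),
                 fbios = character(0)) {
  tibble::tibble(id = id, texts = list(texts), liked_texts = list(liked),
                 followee_bios = list(fbios))
}

test_that("raw interests count keyword occurrences per source with weights", {
  v <- tiny_vocab()
  a <- acct("a", texts = "counting calories on a strict diet")
  raw <- extract_raw_interests(a, v)
  expect_equal(raw$nutrition, 2)
  expect_equal(raw$fitness, 0)

  empty <- extract_raw_interests(acct("e"), v)
  expect_equal(unlist(empty[, -1]), c(nutrition = 0, fitness = 0, music = 0))

  b <- acct("b", texts = "calories calories", liked = "guitar guitar guitar")
  own_only <- extract_raw_interests(b, v, source_weights = c(1, 0, 0))
  liked_only <- extract_raw_interests(b, v, source_weights = c(0, 1, 0))
  expect_equal(own_only$nutrition, 2); expect_equal(own_only$music, 0)
  expect_equal(liked_only$music, 3); expect_equal(liked_only$nutrition, 0)
})

test_that("per-source item cap limits what is counted", {
  v <- tiny_vocab()
  a <- acct("a", texts = rep("calories", 10))
  expect_equal(extract_raw_interests(a, v, max_items = 3)$nutrition, 3)
})

test_that("min-max normalization: global, per-owner, degenerate", {
  tbl <- tibble::tibble(owner_id = c("a", "b", "c"),
                        t1 = c(2, 5, 8), t2 = c(2, 5, 8))
  g <- minmax_normalize(tbl, "global")
  expect_equal(g$t1, c(0, 0.5, 1))

  const <- tibble::tibble(owner_id = "a", t1 = 3, t2 = 3)
  expect_equal(unlist(minmax_normalize(const, "per_owner")[, -1]),
               c(t1 = 0, t2 = 0))

  po <- tibble::tibble(owner_id = c("a", "b"),
                       t1 = c(0, 0), t2 = c(2, 4), t3 = c(4, 8))
  n <- minmax_normalize(po, "per_owner")
  expect_equal(n$t3, c(1, 1))
  expect_equal(n$t2, c(0.5, 0.5))

  expect_error(minmax_normalize(tibble::tibble(owner_id = "a", t1 = -1)),
               "non-negative")
})

test_that("normalizing an already-normalized cohort with full range is a no-op", {
  tbl <- tibble::tibble(owner_id = c("a", "b"), t1 = c(0, 1), t2 = c(0.3, 0.7))
  expect_equal(minmax_normalize(tbl, "global"), tbl)
})

test_that("content score matches an independent cosine oracle and its identities", {
  v_u <- c(0.8, 0.1, 0.5); v_cx <- c(0.7, 0.2, 0.4)
  expect_equal(content_score(v_u, v_cx), oracle_cosine(v_u, v_cx),
               tolerance = 1e-12)
  expect_equal(content_score(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(content_score(c(1, 0), c(0, 1)), 0)
  expect_equal(content_score(c(0, 0), c(1, 1)), 0)
  expect_error(content_score(c(1, 2), c(1, 2, 3)), "same length")
})

test_that("content score is symmetric, bounded and scale-invariant", {
  set.seed(5)
  for (i in 1:25) {
    a <- runif(6); b <- runif(6)
    s <- content_score(a, b)
    expect_equal(s, content_score(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(content_score(3.7 * a, b), s, tolerance = 1e-12)
  }
})

test_that("survey profiles propagate scores to keywords and related concepts", {
  # a second rated subcategory keeps the per-owner range non-degenerate
  v2 <- topic_vocabulary(
    list("video games" = "video games", playstation = "PlayStation",
         music = "music"),
    topics = c("video games", "PlayStation", "game console", "music")
  )
  resp2 <- list(
    participant_id = "par1",
    subcategory_scores = c("video games" = 4, music = 1),
    free_keywords = list("video games" = "PlayStation")
  )
  prof2 <- expand_survey_profile(resp2, v2,
                                 concept_map = list(PlayStation = "game console"))
  expect_equal(prof2$`video games`, 1)
  expect_equal(prof2$PlayStation, 1)
  expect_equal(prof2$`game console`, 1)
  expect_lt(prof2$music, 1)

  zero <- expand_survey_profile(
    list(participant_id = "p", subcategory_scores = c(music = 0)), v2
  )
  expect_equal(sum(unlist(zero[, -1])), 0)
})

test_that("colliding keyword propagations keep the maximum score", {
  v <- topic_vocabulary(list(a = "A", b = "B"), topics = c("A", "B", "C"))
  resp <- list(
    participant_id = "p",
    subcategory_scores = c(a = 5, b = 2),
    free_keywords = list(a = "kw1", b = "kw2")
  )
  cm <- list(kw1 = "C", kw2 = "C")
  prof <- expand_survey_profile(resp, v, cm)
  # C gets max(5, 2) = 5 -> normalizes to 1 alongside A
  expect_equal(prof$C, 1)
  expect_equal(prof$A, 1)
  expect_lt(prof$B, 1)
})

test_that("unresolvable keywords are skipped with a warning", {
  v <- topic_vocabulary(list(a = "A"), topics = c("A", "B"))
  resp <- list(participant_id = "p", subcategory_scores = c(a = 3),
               free_keywords = list(a = "mystery"))
  expect_warning(expand_survey_profile(resp, v), "mystery")
})

test_that("term ranking orders by frequency with lexicographic ties", {
  texts <- c(rep("diet", 9), rep("exercise", 9), rep("food", 6))
  top <- rank_terms(texts, 3)
  expect_equal(top$term, c("diet", "exercise", "food"))
  expect_equal(top$frequency, c(9L, 9L, 6L))

  expect_equal(nrow(rank_terms(character(0), 5)), 0)
  expect_equal(rank_terms(rep("solo", 4), 1)$term, "solo")
})

test_that("term frequencies sum to the total unigram and bigram count", {
  texts <- c("a b c", "b c d d")
  all_terms <- rank_terms(texts, 100)
  # 3 + 4 unigrams, 2 + 3 bigrams
  expect_equal(sum(all_terms$frequency), 12L)
})
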