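fake_pool <- function(counts) {
  structure(
    list(
      target_id = "u",
      counts = tibble::tibble(candidate_id = names(counts),
                              n = as.integer(counts)),
      total = sum(counts), sampled_ids = names(counts)
    ),
    class = "candidate_pool"
  )
}

test_that("occurrence ratio is multiplicity over pool total", {
  pool <- fake_pool(c(d = 3, e = 1))
  expect_equal(occurrences_ratio(pool, "d"), 0.75)
  expect_equal(occurrences_ratio(pool, "absent"), 0)
  expect_equal(occurrences_ratio(fake_pool(c(solo = 4)), "solo"), 1)
  expect_error(occurrences_ratio(fake_pool(integer(0)), "d"), "empty")
})

test_that("jaccard similarity over followee sets", {
  g <- social_graph(
    tibble::tibble(id = c("u", "x", "a", "b", "c", "d")),
    tibble::tibble(
      follower = c("u", "u", "u", "x", "x", "x"),
      followee = c("a", "b", "c", "b", "c", "d")
    )
  )
  expect_equal(jaccard_sim(g, "u", "x"), 0.5)
  expect_equal(jaccard_sim(g, "u", "u"), 1)
  expect_equal(jaccard_sim(g, "a", "b"), 0)  # both empty
})

test_that("topology score is the mean of jaccard and occurrence ratio", {
  g <- social_graph(
    tibble::tibble(id = c("u", "x", "a", "b", "c", "d")),
    tibble::tibble(
      follower = c("u", "u", "u", "x", "x", "x"),
      followee = c("a", "b", "c", "b", "c", "d")
    )
  )
  pool <- fake_pool(c(x = 3, d = 1))
  expect_equal(topology_score(g, "u", "x", pool), (0.5 + 0.75) / 2)
})

test_that("rank score composes harmlessness, content and topology", {
  con <- content_score(c(0.8, 0.1, 0.5), c(0.7, 0.2, 0.4))
  expect_equal(rank_score(0.9, con, 0.625), 0.9 * (con + 0.625) / 2)
  expect_equal(rank_score(0.9, con, 0.625), 0.72668, tolerance = 1e-4)
  expect_equal(rank_score(0, 0.99, 0.99), 0)
  expect_equal(rank_score(0.8, 0.5, 0.9, pro_recovery = TRUE), 0.40)
  expect_equal(rank_score(0.8, 0.5, 0.9, pro_recovery = TRUE,
                          pro_recovery_uses_harmlessness = FALSE), 0.5)
  expect_error(rank_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("participant rank score is harmlessness times content", {
  expect_equal(participants_rank_score(0.9, 0.6), 0.54)
  expect_equal(participants_rank_score(0.7, 0), 0)
  expect_equal(participants_rank_score(1, 0.33), 0.33)
})

test_that("rank score is monotone in each component", {
  grid <- seq(0, 1, by = 0.25)
  for (h in grid) for (con in grid) for (top in grid) {
    base <- rank_score(h, con, top)
    eps <- 0.2
    if (h + eps <= 1) expect_gte(rank_score(h + eps, con, top), base)
    if (con + eps <= 1) expect_gte(rank_score(h, con + eps, top), base)
    if (top + eps <= 1) expect_gte(rank_score(h, con, top + eps), base)
  }
})

test_that("top-K assembly honours the pro-recovery quota", {
  ranked <- tibble::tibble(
    candidate_id = sprintf("g%02d", 1:30),
    content_score = seq(0.9, 0.32, length.out = 30),
    topology_score = 0.5, harmlessness = 0.8, label = "neutral",
    rank_score = 0.8 * (seq(0.9, 0.32, length.out = 30) + 0.5) / 2,
    is_pro_recovery_slot = FALSE
  )
  pr <- tibble::tibble(
    candidate_id = sprintf("pr%02d", 1:10),
    content_score = seq(1, 0.1, length.out = 10),
    harmlessness = 0.9
  )
  top <- assemble_top_k(ranked, pr, K = 15, quota = 0.2)
  expect_equal(nrow(top), 15)
  expect_equal(sum(top$is_pro_recovery_slot), 3)
  expect_equal(sort(top$candidate_id[top$is_pro_recovery_slot]),
               c("pr01", "pr02", "pr03"))
  expect_false(any(duplicated(top$candidate_id)))
  expect_true(all(diff(top$rank_score) <= 0))

  # no pro-recovery candidates: all slots general, with a warning
  expect_warning(top0 <- assemble_top_k(ranked, NULL, K = 15, quota = 0.2),
                 "backfilling")
  expect_equal(sum(top0$is_pro_recovery_slot), 0)
  expect_equal(nrow(top0), 15)

  # quota zero keeps the plain ranking
  plain <- assemble_top_k(ranked, pr, K = 10, quota = 0)
  expect_equal(plain$candidate_id, sprintf("g%02d", 1:10))
})

test_that("tied rank scores break by ascending candidate id", {
  ranked <- tibble::tibble(
    candidate_id = c("zz", "aa", "mm"),
    content_score = 0.5, topology_score = 0.5, harmlessness = 1,
    label = "neutral", rank_score = 0.5, is_pro_recovery_slot = FALSE
  )
  top <- assemble_top_k(ranked, NULL, K = 3, quota = 0)
  expect_equal(top$candidate_id, c("aa", "mm", "zz"))
})

test_that("full ranking equals exhaustive brute-force scoring on small graphs", {
  for (s in 1:15) {
    tbls <- random_graph_tbls(n_nodes = sample(10:30, 1), p_edge = 0.2,
                              seed = 3000 + s)
    g <- social_graph(tbls$accounts, tbls$edges)
    u <- tbls$accounts$id[1]
    pool <- build_candidate_pool(g, u, constant_scorer(1), pool_size = 1000,
                                 seed = s)
    if (pool$total == 0) next
    set.seed(s)
    topics <- sprintf("t%d", 1:4)
    vec_tbl <- tibble::tibble(owner_id = tbls$accounts$id)
    for (tp in topics) vec_tbl[[tp]] <- runif(nrow(vec_tbl))
    harm <- setNames(runif(nrow(vec_tbl)), tbls$accounts$id)
    scorer <- function(graph, ids) unname(harm[ids])

    ranked <- rank_candidates(g, pool, vec_tbl, scorer,
                              pro_recovery_uses_harmlessness = TRUE)
    K <- min(5L, nrow(ranked))
    top <- assemble_top_k(ranked, NULL, K = K, quota = 0)

    vecs <- lapply(setNames(vec_tbl$owner_id, vec_tbl$owner_id),
                   function(id) as.numeric(vec_tbl[vec_tbl$owner_id == id, topics]))
    oracle_counts <- as.list(setNames(pool$counts$n, pool$counts$candidate_id))
    labels <- setNames(tbls$accounts$label, tbls$accounts$id)
    expect_equal(
      top$candidate_id,
      oracle_top_k(tbls$edges, u, oracle_counts, pool$total, vecs, harm, K,
                   labels)
    )
  }
})
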