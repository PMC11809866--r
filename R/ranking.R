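#' Occurrence ratio of a candidate in a pool
#'
#' The number of times candidate `cx` appears in the pool (its arrival
#' multiplicity) over the pool's total multiplicity. Candidates followed by
#' many accounts in the target's extended neighbourhood score higher.
#'
#' @param pool A [build_candidate_pool()] result with positive total.
#' @param cx Candidate id; a candidate absent from the pool scores 0.
#' @return Ratio in `[0, 1]`.
#' @export
occurrences_ratio <- function(pool, cx) {
  if (pool$total <= 0) abort("pool is empty: occurrence ratio undefined")
  i <- match(cx, pool$counts$candidate_id)
  if (is.na(i)) return(0)
  pool$counts$n[i] / pool$total
}

#' Jaccard similarity of followee sets
#'
#' `|followees(u) intersect followees(cx)| / |followees(u) union
#' followees(cx)|`; 0 when both sets are empty.
#'
#' @param graph A [social_graph()].
#' @param u,cx Account ids.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard_sim <- function(graph, u, cx) {
  a <- followees(graph, u)
  b <- followees(graph, cx)
  un <- length(union(a, b))
  if (un == 0L) return(0)
  length(intersect(a, b)) / un
}

#' Topology score
#'
#' Arithmetic mean of the candidate's [jaccard_sim()] with the target and
#' its [occurrences_ratio()] in the target's pool.
#'
#' @inheritParams jaccard_sim
#' @param pool The target's [build_candidate_pool()].
#' @return Score in `[0, 1]`.
#' @export
topology_score <- function(graph, u, cx, pool) {
  (jaccard_sim(graph, u, cx) + occurrences_ratio(pool, cx)) / 2
}

#' Harmlessness-weighted rank score
#'
#' The rank score of a general candidate is
#' `harmlessness * mean(content, topology)`: the harmlessness factor
#' multiplicatively penalizes candidates likely to be harmful, whatever
#' their similarity to the target. For candidates labeled pro-recovery the
#' topology term is dropped and the score is `harmlessness * content`
#' (pro-recovery accounts are structurally distant from the target's
#' neighbourhood, so their network features would unfairly depress them);
#' with `pro_recovery_uses_harmlessness = FALSE` their score is the bare
#' content score.
#'
#' @param harmlessness,content,topology Component scores in `[0, 1]`.
#' @param pro_recovery Logical: is the candidate labeled pro-recovery?
#' @param pro_recovery_uses_harmlessness Keep the harmlessness factor in
#'   the pro-recovery variant (default TRUE).
#' @return Rank score in `[0, 1]`, never exceeding `harmlessness` (when the
#'   factor applies).
#' @export
rank_score <- function(harmlessness, content, topology,
                       pro_recovery = FALSE,
                       pro_recovery_uses_harmlessness = TRUE) {
  assert_prob(harmlessness, "harmlessness")
  assert_prob(content, "content")
  assert_prob(topology, "topology")
  if (pro_recovery) {
    if (pro_recovery_uses_harmlessness) harmlessness * content else content
  } else {
    harmlessness * (content + topology) / 2
  }
}

#' Participant rank score
#'
#' Survey participants have no platform network, so candidate ranking for
#' them uses only `harmlessness * content`.
#'
#' @param harmlessness,content Component scores in `[0, 1]`.
#' @return Score in `[0, 1]`.
#' @export
participants_rank_score <- function(harmlessness, content) {
  assert_prob(harmlessness, "harmlessness")
  assert_prob(content, "content")
  harmlessness * content
}

#' Score every candidate of a pool
#'
#' Computes, for each sampled candidate of the target's pool, the occurrence
#' ratio, Jaccard similarity, topology score, content score (cosine of
#' normalized interest vectors), harmlessness probability and the combined
#' rank score.
#'
#' @param graph A [social_graph()].
#' @param pool The target's [build_candidate_pool()].
#' @param interests Normalized interest tibble covering the target and the
#'   candidates (see [extract_raw_interests()], [minmax_normalize()]).
#' @param scorer Harmlessness scorer (`function(graph, ids)`), e.g.
#'   [screener_scorer()]; applied to the candidates.
#' @param pro_recovery_uses_harmlessness See [rank_score()].
#' @return Tibble of ranked recommendations, descending `rank_score` with
#'   ties broken by ascending `candidate_id`; columns `candidate_id`,
#'   `occurrences_ratio`, `jaccard`, `topology_score`, `content_score`,
#'   `harmlessness`, `rank_score`, `label`, `is_pro_recovery_slot`.
#' @export
rank_candidates <- function(graph, pool, interests, scorer,
                            pro_recovery_uses_harmlessness = TRUE) {
  u <- pool$target_id
  ids <- pool$sampled_ids
  if (length(ids) == 0L) {
    return(tibble::tibble(
      candidate_id = character(0), occurrences_ratio = numeric(0),
      jaccard = numeric(0), topology_score = numeric(0),
      content_score = numeric(0), harmlessness = numeric(0),
      rank_score = numeric(0), label = character(0),
      is_pro_recovery_slot = logical(0)
    ))
  }
  v_u <- interest_vector(interests, u)
  h <- scorer(graph, ids)
  assert_prob(h, "scorer output")
  lab <- graph$accounts$label[match(ids, graph$accounts$id)]
  rows <- purrr::map2(ids, seq_along(ids), function(cx, i) {
    occ <- occurrences_ratio(pool, cx)
    jac <- jaccard_sim(graph, u, cx)
    top <- (occ + jac) / 2
    con <- content_score(v_u, interest_vector(interests, cx))
    tibble::tibble(
      candidate_id = cx, occurrences_ratio = occ, jaccard = jac,
      topology_score = top, content_score = con, harmlessness = h[i],
      rank_score = rank_score(h[i], con, top,
                              pro_recovery = lab[i] == "pro_recovery",
                              pro_recovery_uses_harmlessness),
      label = lab[i], is_pro_recovery_slot = FALSE
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$rank_score), .data$candidate_id)
}

#' Assemble a top-K list with a pro-recovery quota
#'
#' Reserves `round(quota * K)` slots (half-up) for the highest-scoring
#' pro-recovery candidates and fills the remaining slots with the top
#' general candidates, then merges both sets in descending rank score (ties
#' by ascending id). Pro-recovery accounts rarely reach a harmful user's
#' neighbourhood on their own; the quota guarantees them exposure. If fewer
#' pro-recovery candidates exist than the quota asks for, the shortfall is
#' backfilled with general candidates and a warning is raised.
#'
#' @param ranked Tibble from [rank_candidates()] (general candidates).
#' @param pro_recovery_pool Tibble of pro-recovery candidates with at least
#'   `candidate_id`, `content_score`, `harmlessness` (and optionally
#'   `rank_score`, which is recomputed here); may be empty or NULL.
#' @param K List length (>= 1).
#' @param quota Fraction of slots reserved for pro-recovery accounts,
#'   default 0.2.
#' @param pro_recovery_uses_harmlessness Rank quota candidates by
#'   `harmlessness * content` (default) or bare content.
#' @return Tibble of at most `K` rows, no duplicate ids, descending
#'   `rank_score`; quota entries flagged by `is_pro_recovery_slot`.
#' @export
assemble_top_k <- function(ranked, pro_recovery_pool = NULL, K = 15L,
                           quota = 0.2,
                           pro_recovery_uses_harmlessness = TRUE) {
  if (K < 1L) abort("K must be >= 1")
  if (quota < 0 || quota > 1) abort("quota must be in [0, 1]")
  q <- as.integer(floor(quota * K + 0.5))

  pr <- pro_recovery_pool
  if (is.null(pr) || nrow(pr) == 0L) {
    pr <- tibble::tibble(candidate_id = character(0),
                         content_score = numeric(0),
                         harmlessness = numeric(0))
  }
  pr <- dplyr::mutate(
    pr,
    rank_score = purrr::map2_dbl(
      .data$harmlessness, .data$content_score,
      function(h, c) rank_score(h, c, 0, pro_recovery = TRUE,
                                pro_recovery_uses_harmlessness)
    ),
    label = "pro_recovery",
    is_pro_recovery_slot = TRUE
  )
  pr <- dplyr::arrange(pr, dplyr::desc(.data$rank_score), .data$candidate_id)
  pr_take <- utils::head(pr, q)
  if (q > 0L && nrow(pr_take) < q) {
    warn(sprintf(
      "pro-recovery quota asked for %d but only %d candidate(s) available; backfilling with general candidates",
      q, nrow(pr_take)
    ))
  }

  gen <- ranked[!ranked$candidate_id %in% pr_take$candidate_id, ]
  gen <- dplyr::arrange(gen, dplyr::desc(.data$rank_score), .data$candidate_id)
  gen_take <- utils::head(gen, K - nrow(pr_take))

  out <- dplyr::bind_rows(pr_take, gen_take)
  out <- dplyr::arrange(out, dplyr::desc(.data$rank_score), .data$candidate_id)
  out <- dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
  out
}
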