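#' Build a directed follow graph
#'
#' Bundles an account table and a directed edge list into a `social_graph`
#' object. Edges point follower -> followee: the row `(u, v)` means account
#' `u` follows account `v`. Accounts carry the text sources used elsewhere
#' for screening and interest extraction, plus a ground-truth type label
#' where one is known. "Harmless" is never stored as a label: it is defined
#' as the union of `neutral` and `pro_recovery` and computed on demand
#' (see [is_harmless()]).
#'
#' @param accounts A data frame with at least an `id` column (unique
#'   character ids). Optional columns: `label` (one of `"harmful"`,
#'   `"neutral"`, `"pro_recovery"`, `"unknown"`; default `"unknown"`),
#'   `texts` and `liked_texts` (list-columns of character vectors),
#'   `bio` (character), `followee_bios` (list-column of character vectors),
#'   `is_target` (logical). Missing optional columns are filled with empty
#'   defaults.
#' @param edges A data frame with columns `follower` and `followee`.
#'   Self-loops are rejected; duplicated edges are dropped with a warning.
#' @return An object of class `social_graph`: a list with tibbles
#'   `accounts` and `edges` plus precomputed adjacency indexes.
#' @examples
#' g <- social_graph(
#'   accounts = tibble::tibble(id = c("u", "a", "b")),
#'   edges = tibble::tibble(follower = c("u", "u"), followee = c("a", "b"))
#' )
#' followees(g, "u")
#' @export
social_graph <- function(accounts, edges = NULL) {
  accounts <- tibble::as_tibble(accounts)
  if (!"id" %in% names(accounts)) abort("accounts must have an `id` column")
  accounts$id <- as.character(accounts$id)
  if (anyDuplicated(accounts$id)) {
    abort(sprintf(
      "duplicate account id(s): %s",
      paste(unique(accounts$id[duplicated(accounts$id)]), collapse = ", ")
    ))
  }
  n <- nrow(accounts)
  if (!"label" %in% names(accounts)) accounts$label <- rep("unknown", n)
  bad <- setdiff(unique(accounts$label), account_labels())
  if (length(bad)) {
    abort(sprintf(
      "unknown account label(s): %s (harmless is computed, never stored)",
      paste(bad, collapse = ", ")
    ))
  }
  if (!"texts" %in% names(accounts)) accounts$texts <- rep(list(character(0)), n)
  if (!"liked_texts" %in% names(accounts)) accounts$liked_texts <- rep(list(character(0)), n)
  if (!"followee_bios" %in% names(accounts)) accounts$followee_bios <- rep(list(character(0)), n)
  if (!"bio" %in% names(accounts)) accounts$bio <- rep("", n)
  if (!"is_target" %in% names(accounts)) accounts$is_target <- rep(FALSE, n)
  accounts$bio[is.na(accounts$bio)] <- ""
  canonical <- c("id", "label", "texts", "liked_texts", "bio",
                 "followee_bios", "is_target")
  accounts <- accounts[, c(canonical, setdiff(names(accounts), canonical))]

  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(follower = character(0), followee = character(0))
  } else {
    edges <- tibble::as_tibble(edges)[, c("follower", "followee")]
    edges$follower <- as.character(edges$follower)
    edges$followee <- as.character(edges$followee)
    if (any(edges$follower == edges$followee)) abort("self-loops are not allowed")
    missing <- setdiff(unique(c(edges$follower, edges$followee)), accounts$id)
    if (length(missing)) {
      abort(sprintf(
        "edge endpoint(s) not in accounts: %s",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
    dup <- duplicated(paste(edges$follower, edges$followee, sep = "\r"))
    if (any(dup)) {
      warn(sprintf("dropping %d duplicated edge(s)", sum(dup)))
      edges <- edges[!dup, ]
    }
  }

  structure(
    list(
      accounts = accounts,
      edges = edges,
      out_adj = split(edges$followee, factor(edges$follower, levels = accounts$id)),
      in_adj = split(edges$follower, factor(edges$followee, levels = accounts$id))
    ),
    class = "social_graph"
  )
}

account_labels <- function() c("harmful", "neutral", "pro_recovery", "unknown")

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf(
    "<social_graph> %d accounts, %d directed edges\n",
    nrow(x$accounts), nrow(x$edges)
  ))
  tab <- table(x$accounts$label)
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

check_id <- function(graph, u) {
  if (!u %in% graph$accounts$id) abort(sprintf("unknown account id: %s", u))
  invisible(u)
}

#' Followees and followers of an account
#'
#' `followees(g, u)` returns the accounts `u` follows (out-neighbours);
#' `followers(g, u)` the accounts following `u` (in-neighbours). Results are
#' sorted character vectors and never contain `u` itself.
#'
#' @param graph A [social_graph()].
#' @param u An account id present in the graph.
#' @return Sorted character vector of account ids.
#' @export
followees <- function(graph, u) {
  check_id(graph, u)
  sort(unique(graph$out_adj[[u]]))
}

#' @rdname followees
#' @export
followers <- function(graph, u) {
  check_id(graph, u)
  sort(unique(graph$in_adj[[u]]))
}

#' Is an account harmless?
#'
#' Harmless is defined as the union of the `neutral` and `pro_recovery`
#' ground-truth labels; it is a derived predicate, never a stored label.
#'
#' @param label Character vector of account labels.
#' @return Logical vector.
#' @export
is_harmless <- function(label) label %in% c("neutral", "pro_recovery")

#' Account subset retained by a harmlessness scorer
#'
#' Applies a harmlessness scoring function to a set of accounts and keeps
#' those scoring at or above `threshold`. This is the prior filtering step
#' applied to a target user's followees before the candidate pool is
#' expanded, so that harmful accounts do not seed the neighbourhood.
#'
#' @param graph A [social_graph()].
#' @param ids Character vector of account ids to score.
#' @param scorer A function `function(graph, ids)` returning one probability
#'   in `[0, 1]` per id (the harmless-class probability). See
#'   [label_scorer()], [constant_scorer()], [screener_scorer()].
#' @param threshold Retention threshold in `[0, 1]`; default 0.5.
#' @return Sorted character vector of retained ids.
#' @export
filter_harmless <- function(graph, ids, scorer, threshold = 0.5) {
  assert_prob(threshold, "threshold")
  ids <- sort(unique(as.character(ids)))
  if (length(ids) == 0L) return(character(0))
  for (id in ids) check_id(graph, id)
  s <- as.numeric(scorer(graph, ids))
  if (length(s) != length(ids)) abort("scorer must return one score per id")
  assert_prob(s, "scorer output")
  ids[s >= threshold]
}

#' Harmlessness scorers for pool filtering
#'
#' `label_scorer()` scores from ground-truth labels (1 for neutral or
#' pro-recovery, 0 otherwise) -- useful for tests and upper-bound analyses.
#' `constant_scorer(p)` returns `p` for every account (with `p = 1` the
#' filter is a no-op, giving the unfiltered baseline pool).
#' A trained classifier is wrapped with [screener_scorer()].
#'
#' @param p Constant probability in `[0, 1]`.
#' @return A function `function(graph, ids) -> numeric`.
#' @export
label_scorer <- function() {
  function(graph, ids) {
    lab <- graph$accounts$label[match(ids, graph$accounts$id)]
    as.numeric(is_harmless(lab))
  }
}

#' @rdname label_scorer
#' @export
constant_scorer <- function(p = 1) {
  assert_prob(p, "p")
  function(graph, ids) rep(p, length(ids))
}

#' Harmlessness-filtered multi-hop candidate pool
#'
#' Expands the neighbourhood of target user `u` to build the pool of
#' candidate accounts eligible for recommendation. Level 1 is `u`'s
#' followees restricted by [filter_harmless()]; level 2 are the followees of
#' the retained level-1 accounts; candidates are the accounts reached at
#' `depth` hops (default 3, i.e. followees of level-2 accounts). A
#' candidate's multiplicity is the number of previous-level accounts that
#' follow it -- candidates followed by many of `u`'s extended neighbourhood
#' appear more often in the pool, which downstream scoring exploits via the
#' occurrence ratio. The target itself and accounts `u` already follows are
#' never eligible.
#'
#' From the eligible candidates, `pool_size` distinct ids are drawn
#' uniformly without replacement under `seed` (all of them if fewer are
#' eligible); pre-sampling multiplicities are retained for the sampled ids
#' and their sum is the pool total.
#'
#' @inheritParams filter_harmless
#' @param u Target account id.
#' @param depth Hop count at which candidates live; must be >= 2, default 3.
#' @param pool_size Maximum number of distinct sampled candidates,
#'   default 100.
#' @param seed Integer seed for the sampling draw; identical inputs and seed
#'   give identical pools.
#' @return A `candidate_pool` object: list with `target_id`, `counts`
#'   (tibble `candidate_id`, `n`), `total`, `sampled_ids`, and the filter
#'   metadata. An empty pool (no surviving neighbourhood) is valid.
#' @export
build_candidate_pool <- function(graph, u, scorer = constant_scorer(1),
                                 threshold = 0.5, depth = 3L,
                                 pool_size = 100L, seed = 1L) {
  check_id(graph, u)
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 2L) abort("depth must be an integer >= 2")
  if (pool_size < 1L) abort("pool_size must be >= 1")

  direct <- followees(graph, u)
  level <- filter_harmless(graph, direct, scorer, threshold)
  # walk unfiltered levels 2..depth-1; drop u so paths never loop through it
  if (depth > 2L) {
    for (k in seq_len(depth - 2L)) {
      level <- setdiff(
        sort(unique(unlist(graph$out_adj[level], use.names = FALSE))), u
      )
    }
  }
  # arrivals at the final hop, one per (parent at depth-1, candidate) edge
  arrivals <- unlist(graph$out_adj[level], use.names = FALSE)
  arrivals <- arrivals[!arrivals %in% c(u, direct)]

  if (length(arrivals) == 0L) {
    counts <- tibble::tibble(candidate_id = character(0), n = integer(0))
    sampled <- character(0)
  } else {
    tab <- table(arrivals)
    eligible <- sort(names(tab))
    sampled <- if (length(eligible) <= pool_size) {
      eligible
    } else {
      sort(with_seed(seed, sample(eligible, pool_size)))
    }
    counts <- tibble::tibble(
      candidate_id = sampled,
      n = as.integer(tab[sampled])
    )
  }

  structure(
    list(
      target_id = u,
      counts = counts,
      total = sum(counts$n),
      sampled_ids = sampled,
      depth = depth,
      pool_size = as.integer(pool_size),
      threshold = threshold,
      seed = as.integer(seed)
    ),
    class = "candidate_pool"
  )
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf(
    "<candidate_pool> target %s: %d sampled candidates, total multiplicity %d (depth %d)\n",
    x$target_id, length(x$sampled_ids), x$total, x$depth
  ))
  invisible(x)
}

#' @export
tidy.candidate_pool <- function(x, ...) {
  dplyr::mutate(x$counts, target_id = x$target_id, .before = 1)
}
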