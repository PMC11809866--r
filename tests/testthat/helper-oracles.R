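# Independent oracles: deliberately naive implementations used to check the
# package's results. They share no code with the implementation under test.

`%||%` <- function(a, b) if (is.null(a)) b else a

# cosine similarity by explicit summation loops
oracle_cosine <- function(a, b) {
  dot <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    dot <- dot + a[i] * b[i]
    na <- na + a[i]^2
    nb <- nb + b[i]^2
  }
  if (na == 0 || nb == 0) return(0)
  dot / (sqrt(na) * sqrt(nb))
}

# multiset of depth-3 candidate arrivals by exhaustive path enumeration over
# an edge tibble: u -> l1 (retained) -> l2 -> candidate, counting distinct-l2
# parent edges per candidate; excludes u and u's direct followees
oracle_pool_counts <- function(edges, u, retained_l1) {
  out_of <- function(v) unique(edges$followee[edges$follower == v])
  direct <- out_of(u)
  l2 <- setdiff(unique(unlist(lapply(retained_l1, out_of))), u)
  counts <- list()
  for (w in l2) {
    for (c in out_of(w)) {
      if (c %in% c(u, direct)) next
      counts[[c]] <- (counts[[c]] %||% 0L) + 1L
    }
  }
  counts
}

# exhaustive top-K scoring of every eligible candidate, plain loops;
# pro-recovery-labeled candidates use the harmlessness * content variant
oracle_top_k <- function(edges, u, pool_counts, total, vecs, harm, K,
                         labels = NULL) {
  out_of <- function(v) unique(edges$followee[edges$follower == v])
  fu <- out_of(u)
  scores <- data.frame(id = character(0), score = numeric(0))
  for (cx in names(pool_counts)) {
    fc <- out_of(cx)
    un <- union(fu, fc)
    jac <- if (length(un) == 0) 0 else length(intersect(fu, fc)) / length(un)
    occ <- pool_counts[[cx]] / total
    con <- oracle_cosine(vecs[[u]], vecs[[cx]])
    s <- if (!is.null(labels) && labels[[cx]] == "pro_recovery") {
      harm[[cx]] * con
    } else {
      harm[[cx]] * (con + (jac + occ) / 2) / 2
    }
    scores <- rbind(scores, data.frame(id = cx, score = s))
  }
  scores <- scores[order(-scores$score, scores$id), ]
  head(scores$id, K)
}

# small random directed graph as tibbles, base-R RNG only
random_graph_tbls <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n_nodes))
  from <- rep(ids, each = n_nodes)
  to <- rep(ids, times = n_nodes)
  keep <- from != to & runif(n_nodes^2) < p_edge
  list(
    accounts = tibble::tibble(
      id = ids,
      label = sample(c("harmful", "neutral", "pro_recovery"), n_nodes,
                     replace = TRUE)
    ),
    edges = tibble::tibble(follower = from[keep], followee = to[keep])
  )
}

# random annotated recommendation list
random_annotation <- function(k_max, seed) {
  set.seed(seed)
  tibble::tibble(
    candidate_id = sprintf("c%02d", seq_len(k_max)),
    rank = seq_len(k_max),
    type_label = sample(c("harmful", "neutral", "pro_recovery"), k_max,
                        replace = TRUE),
    followed = runif(k_max) < runif(1)
  )
}

# tiny two-vocabulary corpus for screening tests; divergence d mixes a
# shared vocabulary with class-specific words
planted_corpus <- function(n_pos = 20, n_neg = 30, d = 1, words = 30,
                           seed = 1) {
  set.seed(seed)
  shared <- sprintf("s%02d", 1:20)
  pos_v <- sprintf("p%02d", 1:10)
  neg_v <- sprintf("q%02d", 1:10)
  mk <- function(v) {
    paste(ifelse(runif(words) < d, sample(v, words, replace = TRUE),
                 sample(shared, words, replace = TRUE)), collapse = " ")
  }
  tibble::tibble(
    id = sprintf("u%03d", seq_len(n_pos + n_neg)),
    text = c(replicate(n_pos, mk(pos_v)), replicate(n_neg, mk(neg_v))),
    label = rep(c("pos", "neg"), c(n_pos, n_neg))
  )
}
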