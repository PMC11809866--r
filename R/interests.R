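#' Topic vocabulary for interest extraction
#'
#' A keyword-to-topic mapping used to turn free text into bag-of-topics
#' interest scores. Each keyword (matched as a lowercase token) maps to one
#' or more named topics; the topic order is fixed at construction and
#' defines the coordinate order of every interest vector built from the
#' vocabulary.
#'
#' @param keyword_map Named list: keyword -> character vector of topic
#'   names.
#' @param topics Optional explicit topic ordering; defaults to the sorted
#'   union of mapped topics.
#' @return A `topic_vocabulary` object.
#' @seealso [read_vocabulary()] to load one from YAML/JSON.
#' @export
topic_vocabulary <- function(keyword_map, topics = NULL) {
  if (length(keyword_map) == 0L) abort("keyword_map must be non-empty")
  keyword_map <- lapply(keyword_map, as.character)
  if (any(lengths(keyword_map) == 0L)) {
    abort("every keyword must map to at least one topic")
  }
  names(keyword_map) <- tolower(names(keyword_map))
  seen <- sort(unique(unlist(keyword_map, use.names = FALSE)))
  if (is.null(topics)) {
    topics <- seen
  } else {
    topics <- as.character(topics)
    extra <- setdiff(seen, topics)
    if (length(extra)) {
      abort(sprintf("keyword_map references unknown topic(s): %s",
                    paste(extra, collapse = ", ")))
    }
  }
  structure(list(topics = topics, keyword_map = keyword_map),
            class = "topic_vocabulary")
}

#' @export
print.topic_vocabulary <- function(x, ...) {
  cat(sprintf("<topic_vocabulary> %d topics, %d keywords\n",
              length(x$topics), length(x$keyword_map)))
  invisible(x)
}

# topic counts of one text bundle under a vocabulary, as a named vector
count_topics <- function(texts, vocab) {
  out <- setNames(numeric(length(vocab$topics)), vocab$topics)
  if (length(texts) == 0L) return(out)
  tokens <- unlist(lapply(texts, tokenize), use.names = FALSE)
  if (length(tokens) == 0L) return(out)
  hits <- tokens[tokens %in% names(vocab$keyword_map)]
  if (length(hits) == 0L) return(out)
  tab <- table(hits)
  for (kw in names(tab)) {
    for (tp in vocab$keyword_map[[kw]]) out[tp] <- out[tp] + tab[[kw]]
  }
  out
}

#' Raw topic-interest scores for accounts
#'
#' An account's interests are estimated from three sources: the texts it
#' posted, the texts it liked, and the profile biographies of its followees.
#' Each source contributes keyword-occurrence counts mapped to topics via
#' the vocabulary, combined as a weighted sum; at most `max_items` items per
#' source are used (the first `max_items` on the record).
#'
#' @param accounts Account tibble (as held by a [social_graph()]), with
#'   list-columns `texts`, `liked_texts`, `followee_bios`.
#' @param vocab A [topic_vocabulary()].
#' @param source_weights Non-negative weights for (own texts, liked texts,
#'   followee bios); default `c(1, 1, 1)`.
#' @param max_items Per-source cap on the number of texts used; default 200.
#' @return A tibble with `owner_id` plus one numeric column per topic
#'   (raw, unnormalized scores).
#' @export
extract_raw_interests <- function(accounts, vocab, source_weights = c(1, 1, 1),
                                  max_items = 200L) {
  stopifnot(inherits(vocab, "topic_vocabulary"))
  if (length(source_weights) != 3L || any(source_weights < 0)) {
    abort("source_weights must be three non-negative numbers")
  }
  accounts <- tibble::as_tibble(accounts)
  cap <- function(x) utils::head(x %||% character(0), max_items)
  rows <- purrr::pmap(
    list(accounts$texts, accounts$liked_texts, accounts$followee_bios),
    function(tx, lk, fb) {
      source_weights[1] * count_topics(cap(tx), vocab) +
        source_weights[2] * count_topics(cap(lk), vocab) +
        source_weights[3] * count_topics(cap(fb), vocab)
    }
  )
  mat <- do.call(rbind, rows)
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(owner_id = accounts$id), out)
}

interest_matrix <- function(tbl) {
  m <- as.matrix(tbl[setdiff(names(tbl), "owner_id")])
  rownames(m) <- tbl$owner_id
  m
}

#' Min-max normalization of interest scores
#'
#' Rescales raw topic scores to `[0, 1]`. In `global` mode the minimum and
#' maximum are taken jointly over all (owner, topic) entries of the cohort,
#' expressing each score relative to the whole user base (the convention for
#' platform accounts); `per_topic = TRUE` instead normalizes each topic
#' column against its own range. In `per_owner` mode each owner's scores are
#' scaled by that owner's own min and max (the convention for survey
#' participants). A degenerate range (max equal to min) maps to all zeros.
#'
#' @param tbl Interest tibble from [extract_raw_interests()] (`owner_id` +
#'   topic columns); raw scores must be non-negative.
#' @param mode `"global"` or `"per_owner"`.
#' @param per_topic In global mode, normalize each topic column separately.
#' @return A tibble of the same shape with entries in `[0, 1]`.
#' @export
minmax_normalize <- function(tbl, mode = c("global", "per_owner"),
                             per_topic = FALSE) {
  mode <- match.arg(mode)
  m <- interest_matrix(tbl)
  if (nrow(m) == 0L) return(tbl)
  if (any(m < 0)) abort("raw interest scores must be non-negative")
  scale01 <- function(x, lo, hi) {
    if (hi - lo <= 0) x * 0 else (x - lo) / (hi - lo)
  }
  if (mode == "global") {
    if (per_topic) {
      for (j in seq_len(ncol(m))) m[, j] <- scale01(m[, j], min(m[, j]), max(m[, j]))
    } else {
      m <- scale01(m, min(m), max(m))
    }
  } else {
    for (i in seq_len(nrow(m))) m[i, ] <- scale01(m[i, ], min(m[i, ]), max(m[i, ]))
  }
  dplyr::bind_cols(
    tibble::tibble(owner_id = tbl$owner_id),
    tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  )
}

#' Look up one owner's interest vector
#'
#' @param tbl Interest tibble (`owner_id` + topic columns).
#' @param id Owner id.
#' @return Named numeric vector over topics.
#' @export
interest_vector <- function(tbl, id) {
  i <- match(id, tbl$owner_id)
  if (is.na(i)) abort(sprintf("no interest vector for owner: %s", id))
  m <- interest_matrix(tbl)
  m[i, ]
}

#' Content score: cosine similarity of interest vectors
#'
#' The content affinity between a target user and a candidate is the cosine
#' of the angle between their normalized topic-interest vectors. Vectors are
#' non-negative, so the score lies in `[0, 1]`; if either vector is all
#' zeros the score is 0 by convention.
#'
#' @param v_u,v_cx Numeric interest vectors of equal length (same
#'   vocabulary).
#' @return Cosine similarity in `[0, 1]`.
#' @examples
#' content_score(c(0.8, 0.1, 0.5), c(0.7, 0.2, 0.4))
#' @export
content_score <- function(v_u, v_cx) {
  v_u <- as.numeric(v_u); v_cx <- as.numeric(v_cx)
  if (length(v_u) != length(v_cx)) {
    abort("interest vectors must have the same length")
  }
  nu <- sqrt(sum(v_u^2)); nc <- sqrt(sum(v_cx^2))
  if (nu == 0 || nc == 0) return(0)
  min(1, max(0, sum(v_u * v_cx) / (nu * nc)))
}

#' Interest profile from a survey response
#'
#' Survey participants rate predefined interest subcategories on a 0-5
#' scale and may add free keywords (e.g. rating "video games" 4 and naming
#' "PlayStation"). Each subcategory score is propagated to the topics that
#' subcategory maps to, and each free keyword's score is propagated to the
#' keyword's own topics and to every related concept listed for it in
#' `concept_map`. When several propagations hit the same topic the maximum
#' score is kept, so one enthusiastic keyword is not double-counted. The
#' resulting raw vector is normalized per-owner (the participant's own min
#' and max).
#'
#' @param resp A list with `participant_id`, `subcategory_scores` (named
#'   numeric, values 0-5) and optionally `free_keywords` (named list:
#'   subcategory -> character keywords; each keyword inherits its
#'   subcategory's score).
#' @param vocab A [topic_vocabulary()] whose keywords include the
#'   subcategory names (and ideally the free keywords).
#' @param concept_map Named list: keyword -> character vector of related
#'   concept topics. Keywords resolvable through neither `concept_map` nor
#'   `vocab` are skipped with a warning.
#' @return One-row interest tibble (`owner_id` + topic columns), normalized
#'   to `[0, 1]`.
#' @export
expand_survey_profile <- function(resp, vocab, concept_map = list()) {
  stopifnot(inherits(vocab, "topic_vocabulary"))
  scores <- resp$subcategory_scores
  if (any(scores < 0 | scores > 5)) abort("subcategory scores must be in 0..5")
  raw <- setNames(numeric(length(vocab$topics)), vocab$topics)
  bump <- function(topics, s) {
    topics <- intersect(topics, vocab$topics)
    raw[topics] <<- pmax(raw[topics], s)
  }
  resolve <- function(kw) {
    kw_lc <- tolower(kw)
    out <- character(0)
    if (kw %in% vocab$topics) out <- c(out, kw)
    if (kw_lc %in% names(vocab$keyword_map)) out <- c(out, vocab$keyword_map[[kw_lc]])
    if (kw %in% names(concept_map)) out <- c(out, concept_map[[kw]])
    if (kw_lc %in% names(concept_map)) out <- c(out, concept_map[[kw_lc]])
    unique(out)
  }
  for (sub in names(scores)) {
    s <- scores[[sub]]
    if (s <= 0) next
    tps <- resolve(sub)
    if (length(tps) == 0L) {
      warn(sprintf("unresolvable subcategory skipped: %s", sub))
      next
    }
    bump(tps, s)
    for (kw in resp$free_keywords[[sub]] %||% character(0)) {
      ktps <- resolve(kw)
      if (length(ktps) == 0L) {
        warn(sprintf("unresolvable keyword skipped: %s", kw))
        next
      }
      bump(ktps, s)
    }
  }
  tbl <- dplyr::bind_cols(
    tibble::tibble(owner_id = as.character(resp$participant_id)),
    tibble::as_tibble(as.data.frame(t(raw), check.names = FALSE))
  )
  minmax_normalize(tbl, mode = "per_owner")
}

#' Rank terms of a text collection by frequency
#'
#' Counts unigrams and bigrams over the tokenized texts and returns the
#' `top_n` most frequent, ties broken lexicographically. This is the
#' frequency ranking behind topic/term comparison tables and word clouds.
#'
#' @param texts Character vector of texts.
#' @param top_n Number of terms to return (>= 1).
#' @return Tibble with columns `term`, `frequency`, ordered by descending
#'   frequency then term.
#' @export
rank_terms <- function(texts, top_n = 10L) {
  if (top_n < 1L) abort("top_n must be >= 1")
  grams <- unlist(
    lapply(texts, function(t) ngrams(tokenize(t), 1L, 2L)),
    use.names = FALSE
  )
  if (length(grams) == 0L) {
    return(tibble::tibble(term = character(0), frequency = integer(0)))
  }
  tab <- table(grams)
  out <- tibble::tibble(term = names(tab), frequency = as.integer(tab))
  out <- dplyr::arrange(out, dplyr::desc(.data$frequency), .data$term)
  utils::head(out, top_n)
}
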