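synthetic_groups <- function() c("target", "harmful", "neutral", "pro_recovery")

#' Built-in topic vocabulary for synthetic scenarios
#'
#' Eight topics with eight keywords each, covering the vocabulary spheres
#' the generator plants: harm-adjacent topics (nutrition, fitness, body
#' image), recovery-oriented topics (recovery, wellbeing) and neutral
#' topics (music, gaming, news). Every keyword maps to exactly one topic.
#'
#' @return A [topic_vocabulary()].
#' @export
synthetic_vocabulary <- function() {
  kw <- list(
    nutrition = c("calories", "diet", "fasting", "meal", "carbs", "sugar",
                  "vegan", "recipes"),
    fitness = c("exercise", "workout", "running", "gym", "cardio", "steps",
                "training", "sweat"),
    body_image = c("thin", "weight", "mirror", "skinny", "waist", "scale",
                   "bones", "collarbone"),
    recovery = c("recovery", "therapy", "healing", "support", "relapse",
                 "treatment", "hope", "progress"),
    wellbeing = c("mindfulness", "sleep", "balance", "selfcare",
                  "breathing", "journal", "calm", "gratitude"),
    music = c("guitar", "concert", "playlist", "album", "band", "lyrics",
              "piano", "festival"),
    gaming = c("playstation", "console", "gamer", "quest", "pixel",
               "arcade", "level", "stream"),
    news = c("headline", "politics", "election", "economy", "weather",
             "report", "press", "media")
  )
  keyword_map <- list()
  for (tp in names(kw)) for (w in kw[[tp]]) keyword_map[[w]] <- tp
  topic_vocabulary(keyword_map, topics = names(kw))
}

shared_vocabulary <- function() {
  c("the", "and", "today", "really", "just", "think", "about", "people",
    "time", "good", "very", "much", "with", "this", "that", "life",
    "feel", "know", "want", "still", "maybe", "never", "always", "thing",
    "going", "some", "more", "look", "here", "day", "week", "friend",
    "home", "work", "again", "right", "sure", "little", "everyone", "new")
}

#' Synthetic study scenario configuration
#'
#' Defines the population the generator emulates: group sizes
#' (contemplation targets, harmful, neutral, pro-recovery accounts), a
#' group-pair follow-probability matrix expressing intra-cluster homophily,
#' the vocabulary-divergence parameter `delta` controlling how separable
#' group languages are (0 = identical token distributions, 1 = purely
#' group-specific topical vocabulary), per-group topic profiles with a
#' concentration exponent, document-length settings, and the logistic
#' follow-propensity coefficients used to simulate follow decisions.
#'
#' @param n_targets,n_harmful,n_neutral,n_pro_recovery Group sizes.
#' @param follow_prob 4x4 matrix of edge probabilities, rows = follower
#'   group, columns = followee group, in the order target, harmful,
#'   neutral, pro_recovery.
#' @param delta Mixture weight of the group-topical vocabulary in `[0, 1]`.
#' @param topic_profiles Named list group -> named topic weights (need not
#'   be normalized).
#' @param topic_concentration Exponent sharpening (`> 1`) or flattening
#'   (`< 1`) the topic profiles.
#' @param n_texts,n_liked,tokens_per_text,bio_tokens Corpus shape.
#' @param beta0,beta_content,beta_harm_affinity Follow-decision logistic
#'   coefficients: `P(follow) = plogis(beta0 + beta_content * content +
#'   beta_harm_affinity * [candidate harmful])`.
#' @param seed Master seed for the scenario.
#' @return A `scenario_config` object (a named list).
#' @export
scenario_config <- function(n_targets = 10L, n_harmful = 60L,
                            n_neutral = 40L, n_pro_recovery = 12L,
                            follow_prob = NULL, delta = 0.8,
                            topic_profiles = NULL, topic_concentration = 1,
                            n_texts = 8L, n_liked = 4L,
                            tokens_per_text = 12L, bio_tokens = 6L,
                            beta0 = -1.2, beta_content = 2.5,
                            beta_harm_affinity = 0.8, seed = 1L) {
  groups <- synthetic_groups()
  if (is.null(follow_prob)) {
    follow_prob <- matrix(
      # target  harmful neutral pro_recovery   (followee ->)
      c(0.02, 0.30, 0.08, 0.02,   # follower: target
        0.03, 0.25, 0.05, 0.01,   # follower: harmful
        0.01, 0.05, 0.20, 0.05,   # follower: neutral
        0.01, 0.01, 0.10, 0.30),  # follower: pro_recovery
      nrow = 4, byrow = TRUE, dimnames = list(groups, groups)
    )
  }
  follow_prob <- as.matrix(follow_prob)
  dimnames(follow_prob) <- list(groups, groups)
  if (any(follow_prob < 0 | follow_prob > 1)) {
    abort("follow probabilities must lie in [0, 1]")
  }
  if (delta < 0 || delta > 1) abort("delta must lie in [0, 1]")
  sizes <- c(n_targets, n_harmful, n_neutral, n_pro_recovery)
  if (any(sizes < 0)) abort("group sizes must be >= 0")
  if (is.null(topic_profiles)) {
    topic_profiles <- list(
      target = c(nutrition = 0.30, fitness = 0.25, body_image = 0.30,
                 recovery = 0.02, wellbeing = 0.03, music = 0.04,
                 gaming = 0.03, news = 0.03),
      harmful = c(nutrition = 0.32, fitness = 0.30, body_image = 0.30,
                  recovery = 0.01, wellbeing = 0.01, music = 0.02,
                  gaming = 0.02, news = 0.02),
      neutral = c(nutrition = 0.04, fitness = 0.04, body_image = 0.01,
                  recovery = 0.01, wellbeing = 0.10, music = 0.30,
                  gaming = 0.25, news = 0.25),
      pro_recovery = c(nutrition = 0.12, fitness = 0.03, body_image = 0.01,
                       recovery = 0.42, wellbeing = 0.32, music = 0.05,
                       gaming = 0.02, news = 0.03)
    )
  }
  structure(
    list(
      n_targets = as.integer(n_targets), n_harmful = as.integer(n_harmful),
      n_neutral = as.integer(n_neutral),
      n_pro_recovery = as.integer(n_pro_recovery),
      follow_prob = follow_prob, delta = delta,
      topic_profiles = topic_profiles,
      topic_concentration = topic_concentration,
      n_texts = as.integer(n_texts), n_liked = as.integer(n_liked),
      tokens_per_text = as.integer(tokens_per_text),
      bio_tokens = as.integer(bio_tokens),
      beta0 = beta0, beta_content = beta_content,
      beta_harm_affinity = beta_harm_affinity,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Default synthetic scenario
#'
#' The shipped study conditions: a small follow network where contemplation
#' targets' neighbourhoods are dominated by harmful accounts (so the
#' unfiltered 3-hop candidate pool is majority-harmful) while the harmless
#' filtering step routes pool expansion through neutral and pro-recovery
#' followees (so the filtered pool is majority-harmless), with
#' `delta = 0.8` vocabulary divergence.
#'
#' @param seed Master seed.
#' @return A [scenario_config()].
#' @export
default_scenario <- function(seed = 1L) scenario_config(seed = seed)

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> targets=%d harmful=%d neutral=%d pro_recovery=%d delta=%.2f seed=%d\n",
    x$n_targets, x$n_harmful, x$n_neutral, x$n_pro_recovery, x$delta, x$seed
  ))
  invisible(x)
}

scenario_members <- function(cfg) {
  groups <- synthetic_groups()
  sizes <- c(cfg$n_targets, cfg$n_harmful, cfg$n_neutral, cfg$n_pro_recovery)
  prefix <- c(target = "t", harmful = "h", neutral = "n", pro_recovery = "p")
  ids <- character(0); grp <- character(0)
  for (i in seq_along(groups)) {
    if (sizes[i] == 0L) next
    ids <- c(ids, sprintf("%s%03d", prefix[[groups[i]]], seq_len(sizes[i])))
    grp <- c(grp, rep(groups[i], sizes[i]))
  }
  tibble::tibble(id = ids, group = grp)
}

#' Generate a synthetic follow graph
#'
#' Directed edges are drawn independently with the group-pair probabilities
#' of the scenario (a stochastic block model), reproducing the intra-cluster
#' homophily of real harm-adjacent communities. Accounts carry ground-truth
#' labels: targets are contemplation-stage accounts (flagged `is_target`
#' and labeled harmful, as contemplation cases are treated by the
#' harmlessness screener), the remaining groups keep their own labels.
#' Fully deterministic under the scenario seed.
#'
#' @param cfg A [scenario_config()].
#' @return A [social_graph()] with empty text fields (see
#'   [generate_corpus()]).
#' @export
generate_graph <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  members <- scenario_members(cfg)
  n <- nrow(members)
  edges <- with_seed(cfg$seed, {
    from <- rep(seq_len(n), each = n)
    to <- rep(seq_len(n), times = n)
    keep <- from != to
    from <- from[keep]; to <- to[keep]
    p <- cfg$follow_prob[cbind(members$group[from], members$group[to])]
    draw <- runif(length(p)) < p
    tibble::tibble(follower = members$id[from[draw]],
                   followee = members$id[to[draw]])
  })
  accounts <- tibble::tibble(
    id = members$id,
    label = ifelse(members$group == "target", "harmful", members$group),
    is_target = members$group == "target"
  )
  g <- social_graph(accounts, edges)
  g$groups <- setNames(members$group, members$id)
  g
}

group_token_sampler <- function(cfg, vocab) {
  shared <- shared_vocabulary()
  profiles <- lapply(cfg$topic_profiles, function(p) {
    p <- p[vocab$topics]
    p <- p^cfg$topic_concentration
    p / sum(p)
  })
  topic_words <- lapply(setNames(vocab$topics, vocab$topics), function(tp) {
    names(vocab$keyword_map)[vapply(vocab$keyword_map,
                                    function(tps) tp %in% tps, TRUE)]
  })
  function(group, n_tokens) {
    prof <- profiles[[group]]
    topical <- runif(n_tokens) < cfg$delta
    out <- character(n_tokens)
    n_top <- sum(topical)
    if (n_top > 0L) {
      tps <- sample(vocab$topics, n_top, replace = TRUE, prob = prof)
      out[topical] <- vapply(tps, function(tp) {
        sample(topic_words[[tp]], 1L)
      }, "")
    }
    if (n_top < n_tokens) {
      out[!topical] <- sample(shared, n_tokens - n_top, replace = TRUE)
    }
    out
  }
}

#' Generate the synthetic text corpus
#'
#' Fills each account's posted texts, liked texts, biography and followee
#' biographies by unigram sampling: each token comes from the account's
#' group-specific topical vocabulary with probability `delta` (topic drawn
#' from the group topic profile, keyword uniform within the topic) and from
#' a shared filler vocabulary otherwise. With `delta = 0` all groups share
#' one token distribution and no classifier can separate them; with
#' `delta = 1` group vocabularies are (nearly) disjoint.
#'
#' @param cfg A [scenario_config()].
#' @param graph A graph from [generate_graph()] built under the same
#'   config.
#' @return The graph with `texts`, `liked_texts`, `bio`, `followee_bios`
#'   filled.
#' @export
generate_corpus <- function(cfg, graph) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(graph, "social_graph"))
  vocab <- synthetic_vocabulary()
  groups <- graph$groups
  if (is.null(groups)) abort("graph was not produced by generate_graph()")
  draw <- group_token_sampler(cfg, vocab)
  acc <- graph$accounts
  with_seed(cfg$seed + 1L, {
    for (i in seq_len(nrow(acc))) {
      grp <- groups[[acc$id[i]]]
      acc$texts[[i]] <- vapply(seq_len(cfg$n_texts), function(j) {
        paste(draw(grp, cfg$tokens_per_text), collapse = " ")
      }, "")
      acc$liked_texts[[i]] <- vapply(seq_len(cfg$n_liked), function(j) {
        paste(draw(grp, cfg$tokens_per_text), collapse = " ")
      }, "")
      acc$bio[i] <- paste(draw(grp, cfg$bio_tokens), collapse = " ")
    }
  })
  graph$accounts <- acc
  # followee bios are read off the finished bios, capped at 200 per account
  bio_of <- setNames(acc$bio, acc$id)
  graph$accounts$followee_bios <- lapply(acc$id, function(id) {
    unname(bio_of[utils::head(followees(graph, id), 200L)])
  })
  graph
}

#' Simulate a full scenario
#'
#' Convenience wrapper: graph, corpus and vocabulary in one call.
#'
#' @param cfg A [scenario_config()].
#' @return List with `graph`, `vocab`, `config`.
#' @export
simulate_scenario <- function(cfg = default_scenario()) {
  g <- generate_corpus(cfg, generate_graph(cfg))
  list(graph = g, vocab = synthetic_vocabulary(), config = cfg)
}

#' Simulate follow decisions on a recommendation list
#'
#' Bernoulli follow decisions with logistic propensity
#' `plogis(beta0 + beta_content * content_score + beta_harm_affinity *
#' [candidate harmful])`. The harm-affinity term reflects the documented
#' attraction of contemplation-stage users to harmful content; with all
#' coefficients zero the follow rate is 0.5.
#'
#' @param cfg A [scenario_config()].
#' @param recommendations Tibble with columns `content_score` and `label`.
#' @param seed Seed for the Bernoulli draws; default derives from the
#'   scenario seed.
#' @return The recommendations with a logical `followed` column and the
#'   underlying `follow_prob` probability.
#' @export
generate_follow_decisions <- function(cfg, recommendations,
                                      seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "scenario_config"))
  rec <- tibble::as_tibble(recommendations)
  eta <- cfg$beta0 + cfg$beta_content * rec$content_score +
    cfg$beta_harm_affinity * as.numeric(rec$label == "harmful")
  p <- plogis(eta)
  rec$follow_prob <- p
  rec$followed <- with_seed(seed, runif(nrow(rec)) < p)
  rec
}

#' Serialize / restore a scenario configuration
#'
#' JSON round-trip of every scenario parameter, for reproducibility
#' manifests.
#'
#' @param cfg A [scenario_config()].
#' @param path File path.
#' @return `read_scenario()` returns a [scenario_config()] identical to
#'   the one written.
#' @export
write_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  out <- unclass(cfg)
  out$follow_prob <- as.data.frame(out$follow_prob)
  # jsonlite drops names of atomic vectors; keep profiles as objects
  out$topic_profiles <- lapply(out$topic_profiles, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp <- as.matrix(raw$follow_prob)
  scenario_config(
    n_targets = raw$n_targets, n_harmful = raw$n_harmful,
    n_neutral = raw$n_neutral, n_pro_recovery = raw$n_pro_recovery,
    follow_prob = fp, delta = raw$delta,
    topic_profiles = lapply(raw$topic_profiles, unlist),
    topic_concentration = raw$topic_concentration,
    n_texts = raw$n_texts, n_liked = raw$n_liked,
    tokens_per_text = raw$tokens_per_text, bio_tokens = raw$bio_tokens,
    beta0 = raw$beta0, beta_content = raw$beta_content,
    beta_harm_affinity = raw$beta_harm_affinity, seed = raw$seed
  )
}
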