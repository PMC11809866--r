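#' Read and write directed edge lists
#'
#' CSV dialect: header `follower,followee`, one directed edge per row,
#' UTF-8. Duplicate edges are deduplicated with a warning; malformed rows
#' (missing fields) raise an error naming the offending row.
#'
#' @param path CSV file path.
#' @param edges Tibble with columns `follower`, `followee`.
#' @return `read_edges()` returns a tibble `follower`, `followee`.
#' @export
read_edges <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  missing <- setdiff(c("follower", "followee"), names(x))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")))
  }
  x <- x[, c("follower", "followee")]
  bad <- which(is.na(x$follower) | is.na(x$followee) |
                 !nzchar(x$follower) | !nzchar(x$followee))
  if (length(bad)) {
    abort(sprintf("%s: malformed edge row(s) at line(s) %s (header is line 1)",
                  path, paste(bad + 1L, collapse = ", ")))
  }
  dup <- duplicated(paste(x$follower, x$followee, sep = "\r"))
  if (any(dup)) {
    warn(sprintf("%s: dropped %d duplicated edge(s)", path, sum(dup)))
    x <- x[!dup, ]
  }
  x
}

#' @rdname read_edges
#' @export
write_edges <- function(edges, path) {
  readr::write_csv(edges[, c("follower", "followee")], path, progress = FALSE)
  invisible(path)
}

#' Read and write account records as JSON lines
#'
#' One JSON object per line with keys `id`, `label`, `texts`,
#' `liked_texts`, `bio` (and optionally `is_target`, `followee_bios`).
#' Missing optional keys get empty defaults on read; the round-trip is
#' lossless.
#'
#' @param path JSONL file path.
#' @param accounts Account tibble (as held by a [social_graph()]).
#' @return `read_accounts_jsonl()` returns an account tibble.
#' @export
read_accounts_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      abort(sprintf("%s: invalid JSON on line %d: %s",
                                    path, i, conditionMessage(e)))
                    })
    if (is.null(rec$id)) abort(sprintf("%s: line %d has no id", path, i))
    tibble::tibble(
      id = as.character(rec$id),
      label = as.character(rec$label %||% "unknown"),
      texts = list(as.character(rec$texts %||% character(0))),
      liked_texts = list(as.character(rec$liked_texts %||% character(0))),
      bio = as.character(rec$bio %||% ""),
      followee_bios = list(as.character(rec$followee_bios %||% character(0))),
      is_target = isTRUE(rec$is_target)
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname read_accounts_jsonl
#' @export
write_accounts_jsonl <- function(accounts, path) {
  accounts <- tibble::as_tibble(accounts)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(accounts))) {
    rec <- list(
      id = accounts$id[i],
      label = accounts$label[i],
      texts = as.list(accounts$texts[[i]]),
      liked_texts = as.list(accounts$liked_texts[[i]]),
      bio = accounts$bio[i],
      followee_bios = as.list(accounts$followee_bios[[i]]),
      is_target = accounts$is_target[i]
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read and write interest-vector matrices
#'
#' CSV with an `owner_id` column plus one numeric column per topic.
#'
#' @param path CSV file path.
#' @param interests Interest tibble (`owner_id` + topic columns).
#' @return `read_interests()` returns the interest tibble.
#' @export
read_interests <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    owner_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"owner_id" %in% names(x)) abort(sprintf("%s: missing owner_id column", path))
  x
}

#' @rdname read_interests
#' @export
write_interests <- function(interests, path) {
  readr::write_csv(interests, path, progress = FALSE)
  invisible(path)
}

#' Read and write annotated recommendation lists
#'
#' CSV with columns `target_id`, `candidate_id`, `rank`, `type_label`,
#' `followed`.
#'
#' @param path CSV file path.
#' @param annotations Annotation tibble.
#' @return `read_annotations()` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    target_id = readr::col_character(),
    candidate_id = readr::col_character(),
    rank = readr::col_integer(),
    type_label = readr::col_character(),
    followed = readr::col_logical()
  ), progress = FALSE)
  need <- c("target_id", "candidate_id", "rank", "type_label", "followed")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing, collapse = ", ")))
  }
  x
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(
    annotations[, c("target_id", "candidate_id", "rank", "type_label",
                    "followed")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report An [evaluate_model()] report (or stacked reports).
#' @param path Output path without extension (or with `.csv`; the JSON
#'   twin replaces the extension).
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, path) {
  base <- sub("\\.(csv|json)$", "", path)
  readr::write_csv(tibble::as_tibble(report), paste0(base, ".csv"),
                   progress = FALSE)
  jsonlite::write_json(tibble::as_tibble(report), paste0(base, ".json"),
                       digits = NA, pretty = TRUE)
  invisible(c(paste0(base, ".csv"), paste0(base, ".json")))
}

#' Read a topic vocabulary or concept map from YAML/JSON
#'
#' Vocabulary files either map each keyword directly to its topic(s), or
#' use the two keys `topics` (ordered list) and `keywords` (keyword ->
#' topic(s)). Concept maps are flat keyword -> related-concept mappings.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `read_vocabulary()` a [topic_vocabulary()];
#'   `read_concept_map()` a named list.
#' @export
read_vocabulary <- function(path) {
  raw <- read_mapping_file(path)
  if (!is.null(raw$keywords)) {
    topic_vocabulary(lapply(raw$keywords, unlist),
                     topics = unlist(raw$topics))
  } else {
    topic_vocabulary(lapply(raw, unlist))
  }
}

#' @rdname read_vocabulary
#' @export
read_concept_map <- function(path) {
  lapply(read_mapping_file(path), unlist)
}

read_mapping_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read a lexicon set from YAML
#'
#' Expected layout: top-level group names, each mapping lexicon names to
#' term lists.
#'
#' @param path YAML file.
#' @return A [lexicon_set()].
#' @export
read_lexicons <- function(path) {
  raw <- yaml::read_yaml(path)
  lexicon_set(lapply(raw, function(g) lapply(g, function(x) tolower(unlist(x)))))
}
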