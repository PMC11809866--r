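#' Annotated recommendation list
#'
#' Evaluation operates on annotated ranked lists: for one target, the
#' ordered candidates, each with a type label (`harmful`, `neutral`,
#' `pro_recovery`) and a flag saying whether the target (or an annotator on
#' their behalf) would follow it.
#'
#' @param x Data frame with columns `candidate_id`, `type_label`,
#'   `followed`, optionally `rank` (defaults to row order) and `target_id`.
#' @return Tibble ordered by rank, validated.
#' @export
annotated_list <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("candidate_id", "type_label", "followed")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("annotated list missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!"rank" %in% names(x)) x$rank <- seq_len(nrow(x))
  bad <- setdiff(unique(x$type_label), c("harmful", "neutral", "pro_recovery"))
  if (length(bad)) {
    abort(sprintf("unlabeled or unknown candidate type(s): %s",
                  paste(bad, collapse = ", ")))
  }
  x$followed <- as.logical(x$followed)
  dplyr::arrange(x, .data$rank)
}

check_k <- function(x, K) {
  if (K < 1L) abort("K must be >= 1")
  if (K > nrow(x)) {
    abort(sprintf("K = %d exceeds the %d annotated positions", K, nrow(x)))
  }
  invisible(K)
}

#' Precision, recall and average precision at K
#'
#' `precision_at_k()`: fraction of the top-K suggestions the target would
#' follow. `recall_at_k()`: follows in the top K over all follows in the
#' annotated list (0 when nothing was followed at all). `average_precision()`
#' is `sum_i P@i * rel(i) / max(1, follows in top K)` over positions
#' `i <= K`; averaged over targets it gives MAP.
#'
#' @param x An [annotated_list()].
#' @param K Evaluation depth, at most the number of annotated positions.
#' @return A number in `[0, 1]`.
#' @export
precision_at_k <- function(x, K) {
  x <- annotated_list(x); check_k(x, K)
  sum(x$followed[seq_len(K)]) / K
}

#' @rdname precision_at_k
#' @export
recall_at_k <- function(x, K) {
  x <- annotated_list(x); check_k(x, K)
  total <- sum(x$followed)
  if (total == 0L) return(0)
  sum(x$followed[seq_len(K)]) / total
}

#' @rdname precision_at_k
#' @export
average_precision <- function(x, K) {
  x <- annotated_list(x); check_k(x, K)
  rel <- x$followed[seq_len(K)]
  if (!any(rel)) return(0)
  prec_at_i <- cumsum(rel) / seq_len(K)
  sum(prec_at_i[rel]) / sum(rel)
}

#' Suggestion- and follow-type ratios at K
#'
#' For each account type (pro-recovery, neutral, harmful, and harmless =
#' neutral + pro-recovery) three families of ratios over the top K:
#' suggested ratios (`*SR`: type count / K), followed-over-suggested ratios
#' (`*FRS`: follows of the type / suggestions of the type, 0 when the type
#' was never suggested), and followed-over-K ratios (`*FRK`: follows of the
#' type / K).
#'
#' @inheritParams precision_at_k
#' @return One-row tibble with columns `PRSR`, `NSR`, `HSR`, `HLSR`,
#'   `PRFRS`, `NFRS`, `HFRS`, `HLFRS`, `PRFRK`, `HLFRK`, `HFRK`.
#' @export
type_ratios <- function(x, K) {
  x <- annotated_list(x); check_k(x, K)
  top <- x[seq_len(K), ]
  n_of <- function(type) sum(top$type_label %in% type)
  f_of <- function(type) sum(top$followed & top$type_label %in% type)
  frs <- function(type) {
    n <- n_of(type)
    if (n == 0L) 0 else f_of(type) / n
  }
  hl <- c("neutral", "pro_recovery")
  tibble::tibble(
    PRSR = n_of("pro_recovery") / K,
    NSR = n_of("neutral") / K,
    HSR = n_of("harmful") / K,
    HLSR = n_of(hl) / K,
    PRFRS = frs("pro_recovery"),
    NFRS = frs("neutral"),
    HFRS = frs("harmful"),
    HLFRS = frs(hl),
    PRFRK = f_of("pro_recovery") / K,
    HLFRK = f_of(hl) / K,
    HFRK = f_of("harmful") / K
  )
}

#' Average precision-harmlessness ratio score (APHR)
#'
#' Harmonic mean of the average precision and the ratio of harmless
#' accounts followed in the top K (HLFRK):
#' `APHR = 2 * AP * HLFRK / (AP + HLFRK)`, 0 when both are 0. The harmonic
#' mean strongly penalizes lists where only harmful accounts are followed,
#' however precise. At cohort level the same formula is applied to MAP and
#' the mean HLFRK.
#'
#' @param ap,hlfrk Values in `[0, 1]`.
#' @return APHR in `[0, 1]`.
#' @examples
#' aphr(0.29, 0.25) # ~0.27
#' @export
aphr <- function(ap, hlfrk) {
  assert_prob(ap, "ap")
  assert_prob(hlfrk, "hlfrk")
  ifelse(ap + hlfrk == 0, 0, 2 * ap * hlfrk / (ap + hlfrk))
}

#' Evaluate one annotated list at K
#'
#' @inheritParams precision_at_k
#' @return One-row tibble: `K`, `P`, `R`, `AP`, the type ratios and `APHR`.
#' @export
evaluate_list <- function(x, K) {
  x <- annotated_list(x)
  ratios <- type_ratios(x, K)
  ap <- average_precision(x, K)
  dplyr::bind_cols(
    tibble::tibble(K = K, P = precision_at_k(x, K), R = recall_at_k(x, K),
                   AP = ap),
    ratios,
    tibble::tibble(APHR = aphr(ap, ratios$HLFRK))
  )
}

#' Evaluate a model over targets and a K grid
#'
#' Evaluates every target's annotated list at each K and averages across
#' targets: `MAP` is the mean AP, the ratio columns are means, and `APHR`
#' is the harmonic mean of MAP and the mean HLFRK. Targets whose lists are
#' shorter than a given K are skipped at that K.
#'
#' @param annotations Tibble with columns `target_id`, `candidate_id`,
#'   `rank`, `type_label`, `followed` (one row per suggested candidate).
#' @param Ks Ascending integer vector of evaluation depths.
#' @param model Model name recorded in the report.
#' @return An `evaluation_report` tibble: one row per K with columns
#'   `model`, `K`, `n_targets`, `P`, `R`, `MAP`, the type ratios, `APHR`.
#' @export
evaluate_model <- function(annotations, Ks = c(5L, 10L, 15L),
                           model = "model") {
  annotations <- tibble::as_tibble(annotations)
  if (is.unsorted(Ks, strictly = TRUE)) abort("Ks must be strictly ascending")
  per_target <- split(annotations, annotations$target_id)
  rows <- purrr::map(Ks, function(K) {
    evals <- purrr::map(per_target, function(tl) {
      tl <- annotated_list(tl)
      if (nrow(tl) < K) return(NULL)
      evaluate_list(tl, K)
    })
    evals <- purrr::compact(evals)
    if (length(evals) == 0L) return(NULL)
    m <- dplyr::bind_rows(evals)
    means <- dplyr::summarise(m, dplyr::across(-"K", mean))
    out <- dplyr::bind_cols(
      tibble::tibble(model = model, K = K, n_targets = nrow(m)),
      dplyr::rename(means, MAP = "AP")
    )
    out$APHR <- aphr(out$MAP, out$HLFRK)
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Compare evaluation reports across models
#'
#' Stacks per-model reports sharing a K grid into one table and flags, for
#' each (metric, K) cell, whether it is the best value among models --
#' higher is better for every metric except the harmful-exposure columns
#' `HSR`, `HFRS` and `HFRK`, where lower is better.
#'
#' @param reports List of [evaluate_model()] reports (or one stacked
#'   tibble).
#' @param digits Decimal digits for the rounded display columns
#'   (half-up, default 2); raw values are retained.
#' @return Long tibble with columns `model`, `K`, `metric`, `value`,
#'   `rounded`, `best`.
#' @export
compare_models <- function(reports, digits = 2) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  if (length(reports) == 0L) abort("no reports to compare")
  tbl <- dplyr::bind_rows(reports)
  grids <- split(tbl$K, tbl$model)
  if (length(unique(lapply(grids, sort))) != 1L) {
    abort("reports must share the same K grid")
  }
  lower_better <- c("HSR", "HFRS", "HFRK")
  long <- tidyr::pivot_longer(
    tbl, -c("model", "K", "n_targets"),
    names_to = "metric", values_to = "value"
  )
  long |>
    dplyr::group_by(.data$K, .data$metric) |>
    dplyr::mutate(
      rounded = round_half_up(.data$value, digits),
      best = dplyr::if_else(
        .data$metric %in% lower_better,
        .data$value == min(.data$value),
        .data$value == max(.data$value)
      )
    ) |>
    dplyr::ungroup()
}

#' @export
glance.evaluation_report <- function(x, ...) {
  kmax <- max(x$K)
  dplyr::select(
    x[x$K == kmax, ],
    "model", "K", "n_targets", "P", "R", "MAP", "HLFRK", "APHR"
  )
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  tidyr::pivot_longer(x, -c("model", "K", "n_targets"),
                      names_to = "metric", values_to = "value")
}

#' Plot an evaluation report over K
#'
#' @param object An [evaluate_model()] report (or stacked reports).
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object,
                                       metrics = c("P", "MAP", "HSR",
                                                   "HLFRK", "APHR"),
                                       ...) {
  long <- tidy(object)
  long <- long[long$metric %in% metrics, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$value,
                                     colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = NULL, x = "K (list length)")
}
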