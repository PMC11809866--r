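#' Screening corpora from a social graph
#'
#' Build the two labeled corpora used by the screening classifiers. Each
#' account is represented by the concatenation of its posted texts.
#' `harmlessness_corpus()` labels accounts `"harmless"` (neutral or
#' pro-recovery) versus `"harmful"`, dropping unlabeled accounts;
#' `contemplation_corpus()` labels target accounts `"contemplation"` versus
#' `"control"`.
#'
#' @param graph A [social_graph()].
#' @return Tibble with columns `id`, `text`, `label` (one row per account).
#' @export
harmlessness_corpus <- function(graph) {
  acc <- graph$accounts
  acc <- acc[acc$label != "unknown", ]
  tibble::tibble(
    id = acc$id,
    text = vapply(acc$texts, paste, "", collapse = " "),
    label = ifelse(is_harmless(acc$label), "harmless", "harmful")
  )
}

#' @rdname harmlessness_corpus
#' @export
contemplation_corpus <- function(graph) {
  acc <- graph$accounts
  tibble::tibble(
    id = acc$id,
    text = vapply(acc$texts, paste, "", collapse = " "),
    label = ifelse(acc$is_target, "contemplation", "control")
  )
}

#' TF-IDF bag-of-n-grams featurization
#'
#' Represents each document by the occurrence counts of its 1-3-grams (all
#' orders in `ngram_range` included), reweighted by smoothed inverse
#' document frequency `idf(t) = ln((1 + N) / (1 + df(t))) + 1` and
#' L2-normalized per row. When `vocabulary`/`idf` are supplied (from a
#' previous fit) the documents are projected onto that fitted space and
#' unseen n-grams are ignored; otherwise the vocabulary is all n-grams
#' observed in `texts`.
#'
#' @param texts Character vector of documents.
#' @param ngram_range Integer pair `(lo, hi)`, default `c(1, 3)`.
#' @param vocabulary,idf Optional fitted vocabulary (character) and idf
#'   weights (numeric, same length) to reuse.
#' @return List with `x` (sparse [Matrix::dgCMatrix-class], rows unit-L2
#'   unless all-zero), `vocabulary`, `idf`, `ngram_range`.
#' @export
tfidf_featurize <- function(texts, ngram_range = c(1L, 3L),
                            vocabulary = NULL, idf = NULL) {
  if (length(texts) == 0L) abort("corpus must be non-empty")
  lo <- as.integer(ngram_range[1]); hi <- as.integer(ngram_range[2])
  doc_grams <- lapply(texts, function(t) ngrams(tokenize(t), lo, hi))
  n <- length(texts)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(doc_grams, use.names = FALSE)))
    df <- integer(length(vocabulary))
    for (g in doc_grams) {
      j <- match(unique(g), vocabulary)
      df[j] <- df[j] + 1L
    }
    idf <- log((1 + n) / (1 + df)) + 1
  } else if (is.null(idf) || length(idf) != length(vocabulary)) {
    abort("a reused vocabulary needs an idf vector of matching length")
  }
  triplets <- purrr::imap(doc_grams, function(g, i) {
    j <- match(g, vocabulary)
    j <- j[!is.na(j)]
    if (length(j) == 0L) return(NULL)
    tab <- table(j)
    list(i = rep(i, length(tab)), j = as.integer(names(tab)),
         x = as.numeric(tab))
  })
  triplets <- purrr::compact(triplets)
  x <- Matrix::sparseMatrix(
    i = unlist(lapply(triplets, `[[`, "i")),
    j = unlist(lapply(triplets, `[[`, "j")),
    x = unlist(lapply(triplets, `[[`, "x")),
    dims = c(n, length(vocabulary)),
    dimnames = list(NULL, vocabulary)
  )
  x <- x %*% Matrix::Diagonal(x = idf)
  norms <- sqrt(Matrix::rowSums(x^2))
  norms[norms == 0] <- 1
  x <- Matrix::Diagonal(x = 1 / norms) %*% x
  colnames(x) <- vocabulary
  list(x = methods::as(x, "CsparseMatrix"), vocabulary = vocabulary,
       idf = idf, ngram_range = c(lo, hi))
}

#' Lexicon sets for interpretable screening features
#'
#' A `lexicon_set` is an ordered collection of term lists grouped by the
#' linguistic or clinical aspect they capture (e.g. linguistic dimensions,
#' affective processes, eating-disorder vocabulary). Each individual lexicon
#' yields one feature column. The demo set shipped with the package
#' (`demo_lexicons.yaml`, a synthetic stand-in built for testing) follows
#' the 24/29/12/10/9 group layout for a total of 84 features.
#'
#' @param groups Named list: group name -> named list of lexicons, each a
#'   character vector of lowercase terms (unigrams or bigrams).
#' @return A `lexicon_set` object.
#' @seealso [read_lexicons()], [demo_lexicons()]
#' @export
lexicon_set <- function(groups) {
  if (length(groups) == 0L) abort("groups must be non-empty")
  feats <- character(0)
  for (gname in names(groups)) {
    lx <- groups[[gname]]
    if (is.null(names(lx)) || any(!nzchar(names(lx)))) {
      abort(sprintf("every lexicon in group '%s' must be named", gname))
    }
    feats <- c(feats, paste(gname, names(lx), sep = "."))
  }
  structure(list(groups = groups, feature_names = feats),
            class = "lexicon_set")
}

#' @export
print.lexicon_set <- function(x, ...) {
  sizes <- vapply(x$groups, length, 0L)
  cat(sprintf("<lexicon_set> %d features (%s)\n", sum(sizes),
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' The synthetic demo lexicon set shipped with the package
#'
#' Loads `inst/extdata/demo_lexicons.yaml`: a synthetic stand-in for
#' clinician-curated screening lexicons, with group sizes 24/29/12/10/9
#' (84 features).
#'
#' @return A [lexicon_set()].
#' @export
demo_lexicons <- function() {
  read_lexicons(system.file("extdata", "demo_lexicons.yaml",
                            package = "safefollow", mustWork = TRUE))
}

#' Lexicon-based featurization
#'
#' Feature `j` of a document is the number of occurrences of lexicon `j`'s
#' terms (matched against the document's unigrams and bigrams) divided by
#' the document's token count; an empty document yields a zero row. Column
#' order follows the lexicon-set order.
#'
#' @param texts Character vector of documents.
#' @param lexicons A [lexicon_set()].
#' @return Dense numeric matrix, one column per lexicon.
#' @export
lexicon_featurize <- function(texts, lexicons) {
  stopifnot(inherits(lexicons, "lexicon_set"))
  flat <- unlist(unname(lapply(lexicons$groups, unname)), recursive = FALSE)
  x <- matrix(0, nrow = length(texts), ncol = length(flat),
              dimnames = list(NULL, lexicons$feature_names))
  for (i in seq_along(texts)) {
    tokens <- tokenize(texts[[i]])
    if (length(tokens) == 0L) next
    grams <- ngrams(tokens, 1L, 2L)
    for (j in seq_along(flat)) {
      x[i, j] <- sum(grams %in% flat[[j]]) / length(tokens)
    }
  }
  x
}

#' SMOTE minority oversampling
#'
#' Augments the minority class to the majority size by interpolation:
#' each synthetic point is `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)`
#' and `x_nn` one of the `k_neighbors` nearest minority neighbours of the
#' minority point `x` (Euclidean distance). Original samples are never
#' modified; synthetic points lie on segments between minority points.
#'
#' @param x Feature matrix (dense or sparse), one row per sample.
#' @param y Class labels, exactly two distinct values.
#' @param k_neighbors Number of minority nearest neighbours considered;
#'   default 5 (capped at minority size - 1).
#' @param seed Integer seed.
#' @return List with augmented `x` (dense matrix) and `y` (character);
#'   original rows first, synthetic rows appended with label equal to the
#'   minority class.
#' @export
smote_oversample <- function(x, y, k_neighbors = 5L, seed = 1L) {
  y <- as.character(y)
  tab <- sort(table(y))
  if (length(tab) != 2L) abort("y must contain exactly two classes")
  minority <- names(tab)[1]
  deficit <- as.integer(tab[2] - tab[1])
  x <- as.matrix(x)
  if (deficit == 0L) return(list(x = x, y = y))
  if (tab[1] < 2L) {
    abort(paste("minority class has a single sample; SMOTE needs >= 2",
                "(duplicate the sample instead)"))
  }
  min_idx <- which(y == minority)
  xm <- x[min_idx, , drop = FALSE]
  k <- min(as.integer(k_neighbors), nrow(xm) - 1L)
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  nn <- matrix(nn, nrow = k)  # k x n_min
  synth <- with_seed(seed, {
    base <- sample(seq_len(nrow(xm)), deficit, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], 0L)
    lam <- runif(deficit)
    xm[base, , drop = FALSE] +
      lam * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  list(x = rbind(x, synth), y = c(y, rep(minority, deficit)))
}

# fit one classifier; y a factor with positive class as second level
fit_classifier <- function(x, y, kind, cv_folds, seed) {
  switch(kind,
    logistic = with_seed(seed, {
      nf <- max(3L, min(cv_folds, min(table(y))))
      glmnet::cv.glmnet(x = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
                        y = y, family = "binomial", alpha = 0, nfolds = nf)
    }),
    random_forest = ranger::ranger(
      x = as.matrix(x), y = y, probability = TRUE,
      num.trees = 300, seed = seed
    ),
    svm = with_seed(seed, e1071::svm(
      x = as.matrix(x), y = y, kernel = "linear", cost = 1,
      probability = TRUE, scale = FALSE
    )),
    abort(sprintf("unknown classifier kind: %s", kind))
  )
}

predict_positive <- function(fit, kind, x, positive) {
  switch(kind,
    logistic = as.numeric(predict(
      fit, newx = methods::as(Matrix::Matrix(as.matrix(x), sparse = TRUE), "CsparseMatrix"),
      s = "lambda.min", type = "response"
    )),
    random_forest = {
      p <- predict(fit, data = as.matrix(x))$predictions
      as.numeric(p[, positive])
    },
    svm = {
      pr <- predict(fit, as.matrix(x), probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, positive])
    }
  )
}

binary_metrics <- function(truth, prob, positive, threshold = 0.5) {
  pred <- ifelse(prob >= threshold, positive, paste0("not_", positive))
  truth_pos <- truth == positive
  pred_pos <- pred == positive
  tp <- sum(truth_pos & pred_pos)
  precision <- if (sum(pred_pos) == 0) 0 else tp / sum(pred_pos)
  recall <- if (sum(truth_pos) == 0) 0 else tp / sum(truth_pos)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  accuracy <- mean(truth_pos == pred_pos)
  tibble::tibble(precision = precision, recall = recall, f1 = f1,
                 accuracy = accuracy)
}

stratified_split <- function(y, prop, seed) {
  with_seed(seed, {
    test <- logical(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_test <- max(1L, round(length(idx) * prop))
      test[sample(idx, n_test)] <- TRUE
    }
    test
  })
}

#' Train a screening classifier
#'
#' Fits a binary text screener (contemplation-stage detection or
#' harmful-versus-harmless detection) with a 70/30 stratified train/test
#' split. Features are either a TF-IDF 1-3-gram bag of words or
#' interpretable lexicon ratios; the training class imbalance is corrected
#' with [smote_oversample()] applied to training data only (inside each
#' cross-validation fold, and to the full training split for the final
#' fit) -- the held-out test split is never oversampled. Cross-validated and
#' test-set precision/recall/F1 for the positive class plus accuracy are
#' reported.
#'
#' @param corpus Tibble with columns `id`, `text`, `label` (two classes,
#'   one row per account; see [harmlessness_corpus()]).
#' @param positive_class The class whose precision/recall/F1 is reported
#'   and whose probability [harmlessness_score()] returns.
#' @param featurizer `"tfidf"` or `"lexicon"`.
#' @param classifier `"logistic"` (ridge, lambda by cross-validated glmnet),
#'   `"random_forest"` (ranger), or `"svm"` (linear kernel, e1071).
#' @param lexicons A [lexicon_set()]; required when
#'   `featurizer = "lexicon"`.
#' @param ngram_range TF-IDF n-gram orders, default `c(1, 3)`.
#' @param test_prop Held-out test fraction, default 0.3.
#' @param cv_folds Cross-validation folds on the training split, default 5.
#' @param oversample Apply SMOTE to training data, default TRUE.
#' @param seed Integer seed controlling the split, oversampling and any
#'   classifier randomness; identical seeds give identical metrics.
#' @return A `screening_model` with fitted parameters, the featurizer
#'   state, and `$metrics` (`$cv`, `$test` tibbles).
#' @export
train_screener <- function(corpus, positive_class,
                           featurizer = c("tfidf", "lexicon"),
                           classifier = c("logistic", "random_forest", "svm"),
                           lexicons = NULL, ngram_range = c(1L, 3L),
                           test_prop = 0.3, cv_folds = 5L,
                           oversample = TRUE, k_neighbors = 5L, seed = 1L) {
  featurizer <- match.arg(featurizer)
  classifier <- match.arg(classifier)
  corpus <- tibble::as_tibble(corpus)
  if (anyDuplicated(corpus$id)) abort("each owner must appear once in the corpus")
  classes <- sort(unique(corpus$label))
  if (length(classes) != 2L) abort("corpus must contain exactly two classes")
  if (!positive_class %in% classes) {
    abort(sprintf("positive_class '%s' not present in corpus", positive_class))
  }
  negative_class <- setdiff(classes, positive_class)
  if (featurizer == "lexicon" && is.null(lexicons)) lexicons <- demo_lexicons()

  is_test <- stratified_split(corpus$label, test_prop, seed)
  train <- corpus[!is_test, ]
  test <- corpus[is_test, ]

  # featurizer state fitted on the training split only
  if (featurizer == "tfidf") {
    ftrain <- tfidf_featurize(train$text, ngram_range)
    state <- list(vocabulary = ftrain$vocabulary, idf = ftrain$idf,
                  ngram_range = ftrain$ngram_range)
    x_train <- ftrain$x
    x_test <- tfidf_featurize(test$text, state$ngram_range,
                              state$vocabulary, state$idf)$x
  } else {
    state <- list(lexicons = lexicons)
    x_train <- lexicon_featurize(train$text, lexicons)
    x_test <- lexicon_featurize(test$text, lexicons)
  }
  as_factor_y <- function(y) factor(y, levels = c(negative_class, positive_class))

  fit_once <- function(x, y, fit_seed) {
    if (oversample) {
      os <- smote_oversample(as.matrix(x), y, k_neighbors, fit_seed)
      x <- os$x; y <- os$y
    }
    fit_classifier(if (is.matrix(x)) x else as.matrix(x),
                   as_factor_y(y), classifier, cv_folds, fit_seed)
  }

  # cross-validated metrics on the training split, oversampling inside folds
  folds <- with_seed(seed + 1L, {
    f <- integer(nrow(train))
    for (cl in classes) {
      idx <- which(train$label == cl)
      f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    f
  })
  cv_prob <- rep(NA_real_, nrow(train))
  for (k in seq_len(cv_folds)) {
    hold <- folds == k
    if (!any(hold) || length(unique(train$label[!hold])) < 2L) next
    fit_k <- fit_once(as.matrix(x_train)[!hold, , drop = FALSE],
                      train$label[!hold], seed + 100L + k)
    cv_prob[hold] <- predict_positive(
      fit_k, classifier, as.matrix(x_train)[hold, , drop = FALSE],
      positive_class
    )
  }
  ok <- !is.na(cv_prob)
  cv_metrics <- binary_metrics(train$label[ok], cv_prob[ok], positive_class)

  fit <- fit_once(as.matrix(x_train), train$label, seed)
  test_prob <- predict_positive(fit, classifier, as.matrix(x_test),
                                positive_class)
  test_metrics <- binary_metrics(test$label, test_prob, positive_class)

  structure(
    list(
      featurizer = featurizer, classifier = classifier, state = state,
      fit = fit, classes = classes, positive_class = positive_class,
      threshold = 0.5, seed = as.integer(seed),
      metrics = list(cv = cv_metrics, test = test_metrics),
      n_train = nrow(train), n_test = nrow(test)
    ),
    class = "screening_model"
  )
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf(
    "<screening_model> %s features + %s; positive class '%s'\n",
    x$featurizer, x$classifier, x$positive_class
  ))
  m <- x$metrics$test
  cat(sprintf(
    "test (n=%d): precision %.2f, recall %.2f, F1 %.2f, accuracy %.2f\n",
    x$n_test, m$precision, m$recall, m$f1, m$accuracy
  ))
  invisible(x)
}

#' @export
tidy.screening_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$metrics$cv, split = "cv", .before = 1),
    dplyr::mutate(x$metrics$test, split = "test", .before = 1)
  ) |>
    tidyr::pivot_longer(-"split", names_to = "metric", values_to = "value")
}

#' @export
glance.screening_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(featurizer = x$featurizer, classifier = x$classifier,
                   positive_class = x$positive_class,
                   n_train = x$n_train, n_test = x$n_test),
    x$metrics$test
  )
}

# featurize new texts in the model's fitted space
model_features <- function(model, texts) {
  if (model$featurizer == "tfidf") {
    as.matrix(tfidf_featurize(texts, model$state$ngram_range,
                              model$state$vocabulary, model$state$idf)$x)
  } else {
    lexicon_featurize(texts, model$state$lexicons)
  }
}

#' Positive-class probability for new texts or accounts
#'
#' `score_texts()` scores raw documents; `harmlessness_score()` scores
#' accounts by the concatenation of their posted texts (the representation
#' the screeners are trained on). For a harmlessness screener the output is
#' the harmless-class probability: the higher the score, the less harmful
#' the account.
#'
#' @param model A fitted [train_screener()] model.
#' @param texts Character vector of documents.
#' @param accounts Account tibble (with `texts` list-column) or a
#'   [social_graph()].
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
score_texts <- function(model, texts) {
  if (!inherits(model, "screening_model")) abort("model must be a fitted screening_model")
  p <- predict_positive(model$fit, model$classifier,
                        model_features(model, texts), model$positive_class)
  pmin(1, pmax(0, p))
}

#' @rdname score_texts
#' @export
harmlessness_score <- function(model, accounts) {
  if (inherits(accounts, "social_graph")) accounts <- accounts$accounts
  score_texts(model, vapply(accounts$texts, paste, "", collapse = " "))
}

#' Wrap a screening model as a pool-filter scorer
#'
#' @param model A fitted [train_screener()] model (positive class
#'   harmless).
#' @return A scorer function usable by [filter_harmless()] and
#'   [build_candidate_pool()].
#' @export
screener_scorer <- function(model) {
  force(model)
  function(graph, ids) {
    acc <- graph$accounts[match(ids, graph$accounts$id), ]
    harmlessness_score(model, acc)
  }
}

#' Select the highest-certainty contemplation cohort
#'
#' Scores accounts with a contemplation screener and keeps those whose
#' contemplation probability exceeds `threshold` (default 0.95), ordered by
#' descending probability with ties broken by ascending id; optionally
#' capped at the `n_max` most certain.
#'
#' @param model A fitted contemplation [train_screener()] model.
#' @param accounts Account tibble or [social_graph()].
#' @param threshold Probability cut-off, default 0.95.
#' @param n_max Optional cap on cohort size.
#' @return Tibble with `id`, `probability`, ordered.
#' @export
select_contemplation_cohort <- function(model, accounts, threshold = 0.95,
                                        n_max = NULL) {
  if (inherits(accounts, "social_graph")) accounts <- accounts$accounts
  p <- harmlessness_score(model, accounts)
  out <- tibble::tibble(id = accounts$id, probability = p)
  out <- out[out$probability > threshold, ]
  out <- dplyr::arrange(out, dplyr::desc(.data$probability), .data$id)
  if (!is.null(n_max)) out <- utils::head(out, n_max)
  out
}
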