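#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (`0.125 -> 0.13` at 2 digits),
#' matching how the reference tables round reported scores. Base R's
#' [round()] uses banker's rounding, which maps 0.125 to 0.12.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.125, 0.2685, 0.0525), 2)
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Lowercase, strip punctuation, split on whitespace. Shared by the TF-IDF
# and lexicon featurizers and by term ranking so counts agree across modules.
tokenize <- function(text) {
  text <- tolower(text)
  text <- gsub("[^[:alnum:][:space:]_]", " ", text)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}

# n-grams of a token vector as space-joined strings, orders lo..hi
ngrams <- function(tokens, lo = 1L, hi = 3L) {
  n <- length(tokens)
  if (n == 0L) return(character(0))
  out <- vector("list", hi - lo + 1L)
  for (k in seq(lo, hi)) {
    if (n < k) break
    idx <- seq_len(n - k + 1L)
    if (k == 1L) {
      out[[k - lo + 1L]] <- tokens
    } else {
      m <- vapply(idx, function(i) paste(tokens[i:(i + k - 1L)], collapse = " "), "")
      out[[k - lo + 1L]] <- m
    }
  }
  unlist(out, use.names = FALSE)
}

# Evaluate `expr` under a private RNG stream so library code never perturbs
# (or depends on) the caller's .Random.seed.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_prob <- function(x, what = "value") {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1]", what))
  }
  invisible(x)
}
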