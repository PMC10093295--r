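#' Construct an explanation object
#'
#' A per-report attribution: at most `k` (word, score) pairs, sorted by
#' absolute score descending (ties lexicographic), for the class the model
#' actually predicted. Explainers never see true labels: they explain the
#' model as is, including its mistakes.
#'
#' @param report_id Report identifier.
#' @param method One of `"LIME"`, `"SHAP"`, `"IG"`.
#' @param predicted_class Class id in `{1, 2, 3}`.
#' @param scores Named numeric vector of per-word-type scores.
#' @param k Maximum number of items retained (default 5).
#' @return An object of class `explanation` with an `items` data frame and
#'   the full `attributions` vector.
#' @export
explanation <- function(report_id, method, predicted_class, scores, k = 5L) {
  stopifnot(method %in% c("LIME", "SHAP", "IG"), predicted_class %in% 1:3)
  items <- top_k_words(scores, k)
  structure(
    list(report_id = report_id, method = method,
         predicted_class = as.integer(predicted_class),
         items = items, attributions = scores),
    class = "explanation"
  )
}

#' @export
print.explanation <- function(x, ...) {
  cat(sprintf("<explanation> %s report=%s predicted=%d\n",
              x$method, x$report_id, x$predicted_class))
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Select the k most important words by absolute score
#'
#' @param attributions Named numeric vector (word -> score); multiple
#'   occurrences of a word type must be pre-summed by the caller.
#' @param k Number of words to keep (`k >= 1`); if larger than the
#'   vocabulary, the full sorted list is returned.
#' @return Data frame with columns `word`, `score`, ordered by `|score|`
#'   descending with lexicographic tie-breaks.
#' @export
top_k_words <- function(attributions, k) {
  stopifnot(k >= 1)
  w <- names(attributions)
  stopifnot(!is.null(w), !anyDuplicated(w))
  ord <- order(-abs(attributions), w)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(word = w[ord], score = as.numeric(attributions[ord]),
             stringsAsFactors = FALSE)
}

# Token sequence with only the word types in `keep` retained
mask_tokens <- function(tokens, keep) tokens[tokens %in% keep]

#' Explain a prediction with LIME
#'
#' Local surrogate explanation over the report's distinct word types.
#' Perturbations are uniformly random word subsets (each type kept or
#' dropped with probability 1/2, all occurrences at once); each perturbed
#' report is scored by the model on the originally predicted class and
#' weighted by `exp(-D^2 / sigma^2)` where `D` is the cosine distance
#' between the presence mask and the full report. A weighted linear model
#' with forward selection of exactly `n_features` words is fit to those
#' scores; the selected coefficients are the importance scores.
#'
#' @param model A fitted classifier adapter.
#' @param report One row of a tokenized corpus (list with `id`, `tokens`) or
#'   a character token vector.
#' @param n_samples Number of sampled masks (`>= 50`); ignored when
#'   `exact = TRUE`.
#' @param kernel_width Kernel width `sigma`; default `0.25 * sqrt(m)` for
#'   `m` distinct words.
#' @param n_features Number of words selected (default 5).
#' @param seed Integer seed.
#' @param exact If `TRUE`, enumerate all `2^m` masks instead of sampling
#'   (only feasible for small `m`); the same weighted regression is solved.
#' @return An [explanation()] with method `"LIME"`.
#' @export
lime_explain <- function(model, report, n_samples = 1000L, kernel_width = NULL,
                         n_features = 5L, seed = 1L, exact = FALSE) {
  rep_ <- as_report(report)
  tokens <- rep_$tokens
  if (!length(tokens)) stop("cannot explain an empty report", call. = FALSE)
  if (!exact && n_samples < 50) stop("`n_samples` must be at least 50", call. = FALSE)
  words <- unique(tokens)
  m <- length(words)
  sigma <- kernel_width %||% (0.25 * sqrt(m))
  pred <- predict_class(model, tokens)
  masks <- if (exact) {
    all_masks(m)
  } else {
    withr::with_seed(as.integer(seed),
      matrix(stats::runif(n_samples * m) < 0.5, nrow = n_samples) * 1)
  }
  docs <- lapply(seq_len(nrow(masks)), function(i) {
    mask_tokens(tokens, words[masks[i, ] == 1])
  })
  y <- predict_proba(model, docs)[, pred]
  ksum <- rowSums(masks)
  cos_sim <- sqrt(ksum / m)
  wts <- exp(-(1 - cos_sim)^2 / sigma^2)
  sel <- forward_select(masks, y, wts, min(n_features, m))
  fit <- stats::lm.wfit(cbind(1, masks[, sel, drop = FALSE]), y, wts)
  scores <- stats::setNames(fit$coefficients[-1], words[sel])
  scores[is.na(scores)] <- 0
  explanation(rep_$id, "LIME", pred, scores, k = n_features)
}

all_masks <- function(m) {
  stopifnot(m <= 20)
  g <- as.matrix(expand.grid(rep(list(0:1), m)))
  dimnames(g) <- NULL
  g
}

# Greedy forward selection of `k` columns minimizing weighted RSS
forward_select <- function(x, y, w, k) {
  selected <- integer()
  candidates <- seq_len(ncol(x))
  for (step in seq_len(k)) {
    best <- NA_integer_
    best_rss <- Inf
    for (j in setdiff(candidates, selected)) {
      cols <- c(selected, j)
      fit <- stats::lm.wfit(cbind(1, x[, cols, drop = FALSE]), y, w)
      rss <- sum(w * fit$residuals^2)
      if (rss < best_rss - 1e-12) {
        best_rss <- rss
        best <- j
      }
    }
    selected <- c(selected, best)
  }
  selected
}

as_report <- function(report) {
  if (is.character(report)) {
    list(id = "report", tokens = report)
  } else if (!is.null(report$tokens)) {
    toks <- report$tokens
    if (is.list(toks)) toks <- toks[[1]]
    list(id = report$id %||% "report", tokens = as.character(toks))
  } else {
    stop("`report` must be a token vector or a tokenized-corpus row",
         call. = FALSE)
  }
}
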