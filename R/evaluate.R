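#' Random oversampling to the majority class count
#'
#' Every class present in the corpus is brought up to the majority class
#' count by duplicating uniformly-with-replacement from that class's own
#' reports. All original reports are retained; an already balanced (or
#' single-class) corpus is returned unchanged.
#'
#' @param corpus Tokenized corpus tibble.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return The oversampled corpus.
#' @export
oversample <- function(corpus, seed = 1L) {
  if (nrow(corpus) == 0) stop("cannot oversample an empty corpus", call. = FALSE)
  counts <- table(corpus$label)
  target <- max(counts)
  if (all(counts == target)) return(corpus)
  withr::with_seed(as.integer(seed), {
    extra <- lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0) return(NULL)
      pool <- which(corpus$label == as.integer(cl))
      corpus[pool[sample.int(length(pool), need, replace = TRUE)], , drop = FALSE]
    })
  })
  do.call(rbind, c(list(corpus), extra))
}

#' Multiclass evaluation metrics
#'
#' Builds the 3x3 confusion matrix (rows = true, cols = predicted) and the
#' audit's metric set: accuracy = correct / total; per-class precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and F1 (harmonic mean), with
#' the conventions that a class never predicted has precision 0 and a class
#' with no true members has recall 0 and F1 0. `average = "macro"`
#' (default) averages the three classes unweighted; `average = "weighted"`
#' weights by true class support and drops classes absent from `y_true`.
#'
#' @param y_true,y_pred Equal-length integer vectors over `{1, 2, 3}`.
#' @param average `"macro"` or `"weighted"`.
#' @return An object of class `eval_result` with fields `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1`, `per_class`, `average`.
#' @export
compute_metrics <- function(y_true, y_pred, average = c("macro", "weighted")) {
  average <- match.arg(average)
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  stopifnot(all(y_true %in% 1:3), all(y_pred %in% 1:3))
  confusion <- matrix(0L, 3, 3, dimnames = list(true = 1:3, predicted = 1:3))
  for (i in seq_along(y_true)) {
    confusion[y_true[i], y_pred[i]] <- confusion[y_true[i], y_pred[i]] + 1L
  }
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = 1:3, support = as.integer(rowSums(confusion)),
                          precision = precision, recall = recall, f1 = f1)
  if (average == "macro") {
    p <- mean(precision); r <- mean(recall); f <- mean(f1)
  } else {
    w <- rowSums(confusion)
    keep <- w > 0
    p <- sum(w[keep] * precision[keep]) / sum(w[keep])
    r <- sum(w[keep] * recall[keep]) / sum(w[keep])
    f <- sum(w[keep] * f1[keep]) / sum(w[keep])
  }
  structure(
    list(confusion = confusion, accuracy = sum(tp) / length(y_true),
         precision = p, recall = r, f1 = f,
         per_class = per_class, average = average,
         y_true = y_true, y_pred = y_pred),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> n=%d  accuracy=%.3f  %s P=%.3f R=%.3f F1=%.3f\n",
              length(x$y_true), x$accuracy, x$average,
              x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

loo_fold_seed <- function(seed, i) derive_seed(seed, paste0("fold", i))

#' Leave-one-out evaluation with in-fold oversampling
#'
#' For each report `i`: oversample the corpus without `i`, fit a fresh
#' classifier via `classifier_factory(train, seed)`, and predict report
#' `i`; the n held-out predictions are aggregated into one
#' [compute_metrics()] result. Oversampling happens inside each fold so no
#' duplicate of the held-out report can enter its own training set. A fold
#' whose training data lack a class simply cannot predict that class.
#'
#' @param corpus Tokenized corpus tibble with at least 2 reports.
#' @param classifier_factory Function(corpus, seed) -> classifier adapter,
#'   e.g. [tfidf_logistic_classifier()] or [majority_classifier()].
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return An `eval_result` (macro-averaged).
#' @export
loo_evaluate <- function(corpus, classifier_factory, seed = 1L) {
  n <- nrow(corpus)
  if (n < 2) stop("leave-one-out needs at least 2 reports", call. = FALSE)
  preds <- integer(n)
  for (i in seq_len(n)) {
    fs <- loo_fold_seed(seed, i)
    train <- oversample(corpus[-i, , drop = FALSE], seed = fs)
    model <- classifier_factory(train, seed = fs)
    preds[i] <- predict_class(model, corpus$tokens[[i]])
  }
  res <- compute_metrics(corpus$label, preds)
  res$ids <- corpus$id
  res
}

#' Prospective hold-out evaluation with weighted metrics
#'
#' Fits a single classifier on the oversampled training corpus and
#' evaluates on a disjoint test corpus, reporting support-weighted
#' precision, recall and F1 (classes absent from the test set are excluded
#' from the weighted average), as appropriate when a rare class has no
#' prospective test reports.
#'
#' @param train_corpus,test_corpus Tokenized corpus tibbles with disjoint
#'   report ids; the test corpus must be nonempty.
#' @inheritParams loo_evaluate
#' @return An `eval_result` (weighted).
#' @export
holdout_evaluate <- function(train_corpus, test_corpus, classifier_factory,
                             seed = 1L) {
  if (nrow(test_corpus) == 0) stop("empty test set", call. = FALSE)
  if (length(intersect(train_corpus$id, test_corpus$id))) {
    stop("train and test corpora must have disjoint report ids", call. = FALSE)
  }
  fs <- derive_seed(seed, "holdout")
  train <- oversample(train_corpus, seed = fs)
  model <- classifier_factory(train, seed = fs)
  preds <- predict_class(model, test_corpus$tokens)
  res <- compute_metrics(test_corpus$label, preds, average = "weighted")
  res$ids <- test_corpus$id
  res
}
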