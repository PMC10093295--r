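#' Construct a differentiable text model
#'
#' The contract required by Integrated Gradients: `embed` maps a token
#' sequence to a numeric input (vector or matrix), `forward` maps that
#' input to a probability vector over the 3 classes, and `gradient` returns
#' the derivative of one class probability with respect to the input, with
#' the input's shape. `forward(embed(tokens))` must agree with the wrapped
#' classifier's `predict_proba` to within 1e-9.
#'
#' @param embed Function(token vector) -> numeric vector or matrix.
#' @param forward Function(input) -> probability vector of length 3.
#' @param gradient Function(input, class) -> numeric of the input's shape.
#' @param input_words Function(input, tokens) -> character vector naming the
#'   word type behind each attribution row/entry (used to aggregate input
#'   dimensions to word types).
#' @return An object of class `differentiable_model`.
#' @export
differentiable_model <- function(embed, forward, gradient, input_words) {
  stopifnot(is.function(embed), is.function(forward), is.function(gradient))
  structure(list(embed = embed, forward = forward, gradient = gradient,
                 input_words = input_words),
            class = "differentiable_model")
}

#' Expose a fitted classifier as a differentiable text model
#'
#' `tfidf_logistic` models embed a report as its TF-IDF vector (one input
#' dimension per vocabulary word, so attributions are per-word already);
#' `embedding_bag` models embed a report as its token-embedding matrix (one
#' row per token; per-token attributions are summed over embedding
#' dimensions and then over occurrences of the same word type).
#'
#' @param object A fitted classifier adapter.
#' @param ... Unused.
#' @return A [differentiable_model()].
#' @export
as_differentiable <- function(object, ...) UseMethod("as_differentiable")

#' @export
as_differentiable.tfidf_logistic <- function(object, ...) {
  if (is.null(object$model)) {
    stop("single-class degenerate model is not differentiable", call. = FALSE)
  }
  differentiable_model(
    embed = function(tokens) tfidf_transform(object$tfidf, tokens),
    forward = function(x) logistic_proba(object$model, x),
    gradient = function(x, class) logistic_gradient(object$model, x, class),
    input_words = function(x, tokens) names(object$tfidf$vocabulary)
  )
}

#' @export
as_differentiable.embedding_bag <- function(object, ...) {
  differentiable_model(
    embed = function(tokens) {
      idx <- match(tokens, object$vocab)
      kept <- tokens[!is.na(idx)]
      idx <- idx[!is.na(idx)]
      x <- object$embeddings[idx, , drop = FALSE]
      rownames(x) <- kept
      x
    },
    forward = function(x) {
      pooled <- if (nrow(x)) colMeans(x) else numeric(object$embed_dim)
      embedding_bag_forward(object, matrix(pooled, nrow = 1))[1, ]
    },
    gradient = function(x, class) {
      n <- nrow(x)
      pooled <- if (n) colMeans(x) else numeric(object$embed_dim)
      g <- embedding_bag_gradient(object, pooled, class)
      # mean pooling: each token row receives 1/n of the pooled gradient
      out <- matrix(rep(g / max(n, 1), each = n), nrow = n)
      rownames(out) <- rownames(x)
      out
    },
    input_words = function(x, tokens) rownames(x)
  )
}
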