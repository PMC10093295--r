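#' Integrated-gradients attribution for a differentiable function
#'
#' Core IG operator: `IG_i = (x_i - x0_i) * mean_{j=1..n_steps}
#' g_i(x0 + ((j - 1/2)/n_steps) * (x - x0))`, a midpoint-rule Riemann
#' approximation of the path integral of the gradient `g` from the baseline
#' `x0` to the input `x` (the midpoint rule converges one order faster than
#' endpoint rules, so the completeness residual falls as `1/n_steps^2`).
#' For a linear function the result is exact for any number of steps; in
#' general the completeness property `sum(IG) = f(x) - f(x0)` holds in the
#' limit of many steps.
#'
#' @param x Numeric input (vector or matrix).
#' @param baseline Baseline input of the same shape; default all zeros.
#' @param gradient Function(input) -> gradient of the scalar of interest,
#'   same shape as the input.
#' @param n_steps Number of Riemann steps (`>= 2`).
#' @return Attributions with the shape of `x`.
#' @export
ig_attribute <- function(x, baseline = NULL, gradient, n_steps = 64L) {
  stopifnot(is.function(gradient), n_steps >= 2)
  x0 <- baseline %||% (x * 0)
  stopifnot(length(x0) == length(x))
  acc <- x * 0
  for (j in seq_len(n_steps)) {
    acc <- acc + gradient(x0 + ((j - 0.5) / n_steps) * (x - x0))
  }
  (x - x0) * acc / n_steps
}

#' Explain a prediction with Integrated Gradients
#'
#' Applies [ig_attribute()] to the predicted-class probability of a
#' differentiable text model, with the all-zero input as default baseline,
#' and aggregates input-dimension attributions to word types by summation.
#'
#' @param model A [differentiable_model()] (see [as_differentiable()]).
#' @param report Token vector or tokenized-corpus row.
#' @param baseline Optional baseline input (same shape as the embedding);
#'   default all zeros.
#' @param n_steps Number of Riemann steps (`>= 2`).
#' @param k Number of items retained (default 5).
#' @return An [explanation()] with method `"IG"`; `attributions` carries
#'   the per-word-type sums for the report's distinct words.
#' @export
integrated_gradients_explain <- function(model, report, baseline = NULL,
                                         n_steps = 64L, k = 5L) {
  if (!inherits(model, "differentiable_model")) {
    stop("`model` must satisfy the differentiable-model contract ",
         "(see as_differentiable())", call. = FALSE)
  }
  rep_ <- as_report(report)
  tokens <- rep_$tokens
  if (!length(tokens)) stop("cannot explain an empty report", call. = FALSE)
  x <- model$embed(tokens)
  probs <- model$forward(x)
  pred <- which.max(probs)
  ig <- ig_attribute(x, baseline, function(z) model$gradient(z, pred), n_steps)
  dim_words <- model$input_words(x, tokens)
  per_dim <- if (is.matrix(ig)) rowSums(ig) else as.numeric(ig)
  stopifnot(length(per_dim) == length(dim_words))
  scores <- tapply(per_dim, dim_words, sum)
  scores <- stats::setNames(as.numeric(scores), names(scores))
  # restrict to word types actually present in the report
  present <- intersect(names(scores), unique(tokens))
  scores <- scores[present]
  missing <- setdiff(unique(tokens), present)
  if (length(missing)) {
    scores <- c(scores, stats::setNames(numeric(length(missing)), missing))
  }
  explanation(rep_$id, "IG", pred, scores, k = k)
}
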