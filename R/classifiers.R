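#' Predict class probabilities from a classifier adapter
#'
#' Every classifier in the audit implements this contract: given one token
#' sequence it returns a probability vector over the three report classes
#' (named `"1"`, `"2"`, `"3"`, nonnegative, summing to 1); given a list of
#' token sequences it returns a matrix with one row per document. Classes
#' absent from the training data receive probability 0.
#'
#' @param object A fitted classifier adapter.
#' @param tokens Character vector (one document) or list of character
#'   vectors.
#' @param ... Passed to methods.
#' @return Numeric vector of length 3, or a matrix `n x 3`.
#' @export
predict_proba <- function(object, tokens, ...) UseMethod("predict_proba")

#' Predict the most probable class
#'
#' @inheritParams predict_proba
#' @return Integer class id(s) in `{1, 2, 3}`; ties break to the lowest id.
#' @export
predict_class <- function(object, tokens, ...) {
  p <- predict_proba(object, tokens, ...)
  if (is.matrix(p)) {
    as.integer(apply(p, 1, which.max))
  } else {
    as.integer(which.max(unname(p)))
  }
}

softmax_rows <- function(eta) {
  eta <- eta - apply(eta, 1, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

expand_to_three <- function(p, classes_present) {
  # p: n x length(classes_present) probabilities -> n x 3 with zeros
  out <- matrix(0, nrow = nrow(p), ncol = 3, dimnames = list(NULL, as.character(1:3)))
  out[, classes_present] <- p
  out
}

#' Majority-class baseline classifier
#'
#' Predicts the most common training class for every report (ties break to
#' the lowest class id); its probability vector equals the training class
#' frequencies. Serves as the practical lower bound for the audit.
#'
#' @param corpus Tokenized corpus tibble (`id`, `tokens`, `label`).
#' @param ... Ignored (accepted so the constructor can serve as a
#'   classifier factory).
#' @return A classifier adapter of class `majority_classifier`.
#' @export
majority_classifier <- function(corpus, ...) {
  stopifnot(nrow(corpus) > 0)
  counts <- tabulate(corpus$label, nbins = 3)
  structure(
    list(probs = stats::setNames(counts / sum(counts), as.character(1:3)),
         predicted = which.max(counts)),
    class = c("majority_classifier", "xaudit_classifier")
  )
}

#' @export
predict_proba.majority_classifier <- function(object, tokens, ...) {
  if (is.list(tokens)) {
    matrix(object$probs, nrow = length(tokens), ncol = 3, byrow = TRUE,
           dimnames = list(NULL, as.character(1:3)))
  } else {
    object$probs
  }
}

#' Fit an L2-penalized multinomial logistic regression
#'
#' Maximizes the L2-penalized multinomial log-likelihood (via
#' `nnet::multinom`, zero-initialized so the fit is deterministic) on a
#' numeric feature matrix. The returned object carries the full coefficient
#' matrix, so predicted probabilities and their analytic input gradients
#' (needed by Integrated Gradients) are available in closed form.
#'
#' @param features Numeric matrix, one row per document.
#' @param labels Integer labels in `{1, 2, 3}`; at least two distinct
#'   classes must be present.
#' @param l2_strength Nonnegative L2 penalty (weight decay) on the total
#'   loss; the default 0.5 matches the conventional unit-strength ridge
#'   penalty `0.5 * ||w||^2` of standard logistic-regression settings.
#' @param seed Unused (the fit is deterministic); kept for the adapter
#'   factory contract.
#' @return An object of class `logistic_model` with fields `coef`
#'   (3 x (p + 1), zero rows for absent classes), `classes_present` and
#'   `converged`.
#' @export
fit_logistic <- function(features, labels, l2_strength = 0.5, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels))
  classes_present <- sort(unique(labels))
  if (length(classes_present) < 2) {
    stop("fit_logistic requires at least two classes present", call. = FALSE)
  }
  y <- factor(labels, levels = classes_present)
  x <- features
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- nnet::multinom(y ~ x, decay = l2_strength, trace = FALSE,
                        maxit = 500, reltol = 1e-12, abstol = 1e-10,
                        MaxNWts = 1e6)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  b_present <- rbind(0, cf) # rows follow classes_present; first level is baseline
  b <- matrix(0, nrow = 3, ncol = ncol(features) + 1)
  b[classes_present, ] <- b_present
  structure(
    list(coef = b, classes_present = classes_present,
         converged = identical(fit$convergence, 0L)),
    class = "logistic_model"
  )
}

# eta over the 3 classes, with -Inf for absent classes so probabilities are 0
logistic_eta <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  eta <- cbind(1, x) %*% t(model$coef)
  absent <- setdiff(1:3, model$classes_present)
  if (length(absent)) eta[, absent] <- -Inf
  eta
}

#' Predicted probabilities of a fitted logistic model on feature vectors
#'
#' @param model A [fit_logistic()] model.
#' @param features Numeric vector or matrix.
#' @return Probability vector or matrix over the 3 classes.
#' @export
logistic_proba <- function(model, features) {
  single <- !is.matrix(features)
  p <- softmax_rows(logistic_eta(model, features))
  colnames(p) <- as.character(1:3)
  if (single) p[1, ] else p
}

#' Analytic gradient of a class probability w.r.t. the input features
#'
#' For `p = softmax(Bx + b)`, `d p_c / d x = p_c (B_c - sum_k p_k B_k)`.
#'
#' @param model A [fit_logistic()] model.
#' @param features Numeric feature vector.
#' @param class Class id whose probability is differentiated.
#' @return Numeric gradient vector, same length as `features`.
#' @export
logistic_gradient <- function(model, features, class) {
  p <- logistic_proba(model, features)
  bw <- model$coef[, -1, drop = FALSE] # 3 x p, weights without intercept
  as.numeric(p[class] * (bw[class, ] - colSums(p * bw)))
}

#' TF-IDF + logistic-regression classifier adapter
#'
#' The audit's reference classical model: fits a TF-IDF weighting on the
#' training corpus and an L2-penalized multinomial logistic regression on
#' the weighted vectors. Folds whose training data contain a single class
#' degenerate to always predicting that class.
#'
#' @param corpus Tokenized corpus tibble.
#' @param seed Passed through to [fit_logistic()] (deterministic anyway).
#' @param l2_strength L2 penalty of the logistic fit.
#' @return A classifier adapter of class `tfidf_logistic`.
#' @export
tfidf_logistic_classifier <- function(corpus, seed = 1L, l2_strength = 0.5) {
  stopifnot(nrow(corpus) > 0)
  tfidf <- fit_tfidf(corpus)
  classes_present <- sort(unique(corpus$label))
  model <- NULL
  if (length(classes_present) >= 2) {
    x <- tfidf_transform(tfidf, corpus$tokens)
    model <- fit_logistic(x, corpus$label, l2_strength = l2_strength, seed = seed)
  }
  structure(
    list(tfidf = tfidf, model = model, classes_present = classes_present),
    class = c("tfidf_logistic", "xaudit_classifier")
  )
}

#' @export
predict_proba.tfidf_logistic <- function(object, tokens, ...) {
  single <- !is.list(tokens)
  docs <- if (single) list(as.character(tokens)) else tokens
  if (is.null(object$model)) {
    p <- expand_to_three(matrix(1, nrow = length(docs), ncol = 1),
                         object$classes_present)
  } else {
    x <- tfidf_transform(object$tfidf, docs)
    p <- logistic_proba(object$model, x)
  }
  colnames(p) <- as.character(1:3)
  if (single) p[1, ] else p
}

#' Embedding-bag neural text classifier
#'
#' A small differentiable model: fixed random word embeddings are
#' mean-pooled into a document vector and fed to a one-hidden-layer tanh
#' network with softmax output, trained by full-batch Adam on the
#' cross-entropy loss with L2 regularization. Gradients of every class
#' probability with respect to the pooled input (and hence each token
#' embedding) are analytic, which makes the model a first-class target for
#' Integrated Gradients.
#'
#' @param corpus Tokenized corpus tibble.
#' @param seed Integer seed for embeddings, weight init and shuffling.
#' @param embed_dim,hidden_dim Embedding and hidden-layer widths.
#' @param epochs Number of full-batch Adam steps.
#' @param learn_rate Adam step size.
#' @param l2 L2 penalty on network weights.
#' @return A classifier adapter of class `embedding_bag`.
#' @export
embedding_bag_classifier <- function(corpus, seed = 1L, embed_dim = 16L,
                                     hidden_dim = 16L, epochs = 300L,
                                     learn_rate = 0.05, l2 = 1e-4) {
  stopifnot(nrow(corpus) > 0)
  vocab <- sort(unique(unlist(corpus$tokens, use.names = FALSE)))
  classes_present <- sort(unique(corpus$label))
  withr::with_seed(as.integer(seed), {
    emb <- matrix(stats::rnorm(length(vocab) * embed_dim, sd = 1 / sqrt(embed_dim)),
                  nrow = length(vocab), dimnames = list(vocab, NULL))
    pool <- function(tokens) {
      idx <- match(tokens, vocab)
      idx <- idx[!is.na(idx)]
      if (!length(idx)) return(numeric(embed_dim))
      colMeans(emb[idx, , drop = FALSE])
    }
    x <- t(vapply(corpus$tokens, pool, numeric(embed_dim)))
    k <- 3L
    y <- matrix(0, nrow(x), k)
    y[cbind(seq_len(nrow(x)), corpus$label)] <- 1
    w1 <- matrix(stats::rnorm(embed_dim * hidden_dim, sd = 0.3), embed_dim, hidden_dim)
    b1 <- numeric(hidden_dim)
    w2 <- matrix(stats::rnorm(hidden_dim * k, sd = 0.3), hidden_dim, k)
    b2 <- numeric(k)
    params <- list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
    mom <- lapply(params, function(p) p * 0)
    vel <- lapply(params, function(p) p * 0)
    n <- nrow(x)
    for (t in seq_len(epochs)) {
      z <- tanh(sweep(x %*% params$w1, 2, params$b1, `+`))
      p <- softmax_rows(sweep(z %*% params$w2, 2, params$b2, `+`))
      dlogits <- (p - y) / n
      grads <- list(
        w1 = t(x) %*% ((dlogits %*% t(params$w2)) * (1 - z^2)) + l2 * params$w1,
        b1 = colSums((dlogits %*% t(params$w2)) * (1 - z^2)),
        w2 = t(z) %*% dlogits + l2 * params$w2,
        b2 = colSums(dlogits)
      )
      for (nm in names(params)) {
        mom[[nm]] <- 0.9 * mom[[nm]] + 0.1 * grads[[nm]]
        vel[[nm]] <- 0.999 * vel[[nm]] + 0.001 * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - 0.9^t)
        vhat <- vel[[nm]] / (1 - 0.999^t)
        params[[nm]] <- params[[nm]] - learn_rate * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  })
  structure(
    list(vocab = vocab, embeddings = emb, params = params,
         embed_dim = embed_dim, classes_present = classes_present),
    class = c("embedding_bag", "xaudit_classifier")
  )
}

embedding_bag_forward <- function(object, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  z <- tanh(sweep(x %*% object$params$w1, 2, object$params$b1, `+`))
  p <- softmax_rows(sweep(z %*% object$params$w2, 2, object$params$b2, `+`))
  colnames(p) <- as.character(1:3)
  p
}

embedding_bag_pool <- function(object, tokens) {
  idx <- match(tokens, object$vocab)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(numeric(object$embed_dim))
  colMeans(object$embeddings[idx, , drop = FALSE])
}

#' @export
predict_proba.embedding_bag <- function(object, tokens, ...) {
  single <- !is.list(tokens)
  docs <- if (single) list(as.character(tokens)) else tokens
  x <- t(vapply(docs, function(d) embedding_bag_pool(object, d),
                numeric(object$embed_dim)))
  p <- embedding_bag_forward(object, x)
  if (single) p[1, ] else p
}

# d p_class / d x for the pooled input of an embedding-bag model
embedding_bag_gradient <- function(object, x, class) {
  z <- tanh(as.numeric(x %*% object$params$w1) + object$params$b1)
  p <- embedding_bag_forward(object, matrix(x, nrow = 1))[1, ]
  e <- numeric(3); e[class] <- 1
  dlogits <- p[class] * (e - p)
  dz <- as.numeric(object$params$w2 %*% dlogits)
  as.numeric(object$params$w1 %*% (dz * (1 - z^2)))
}

#' Wrap a plain function as a classifier adapter
#'
#' Lifts `fn(tokens) -> probability vector over the 3 classes` into the
#' adapter contract, so hand-specified models (oracles, stubs, externally
#' trained classifiers) can be explained and audited like native ones.
#'
#' @param fn Function of one token vector returning a numeric probability
#'   vector of length 3.
#' @return A classifier adapter of class `function_classifier`.
#' @export
function_classifier <- function(fn) {
  stopifnot(is.function(fn))
  structure(list(fn = fn), class = c("function_classifier", "xaudit_classifier"))
}

#' @export
predict_proba.function_classifier <- function(object, tokens, ...) {
  if (is.list(tokens)) {
    p <- t(vapply(tokens, function(d) as.numeric(object$fn(as.character(d))),
                  numeric(3)))
    colnames(p) <- as.character(1:3)
    p
  } else {
    stats::setNames(as.numeric(object$fn(as.character(tokens))),
                    as.character(1:3))
  }
}
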