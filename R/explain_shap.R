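#' Explain a prediction with Kernel SHAP
#'
#' Shapley-value attribution over the report's distinct word types. The
#' value of a coalition `S` is the model's predicted probability of the
#' originally predicted class for the report with only the word types in
#' `S` retained (all other occurrences removed). With `m <= 12` distinct
#' words (or `exact = TRUE`) Shapley values are computed by exhaustive
#' coalition enumeration; otherwise coalitions are sampled proportionally
#' to the Shapley kernel and the values are estimated by weighted least
#' squares under the efficiency constraint
#' `sum(phi) = v(full) - v(empty)`.
#'
#' @inheritParams lime_explain
#' @param n_samples Number of sampled coalitions in the sampling regime.
#' @param exact Force exact enumeration (`TRUE`), sampling (`FALSE`), or
#'   choose by `m <= 12` (`NULL`, default).
#' @param k Number of items retained in the explanation (default 5).
#' @return An [explanation()] with method `"SHAP"`; its `attributions`
#'   field carries the Shapley value of every distinct word.
#' @export
kernel_shap_explain <- function(model, report, n_samples = 2048L, seed = 1L,
                                exact = NULL, k = 5L) {
  rep_ <- as_report(report)
  tokens <- rep_$tokens
  if (!length(tokens)) stop("cannot explain an empty report", call. = FALSE)
  words <- unique(tokens)
  m <- length(words)
  pred <- predict_class(model, tokens)
  value_of <- function(masks) {
    docs <- lapply(seq_len(nrow(masks)), function(i) {
      mask_tokens(tokens, words[masks[i, ] == 1])
    })
    predict_proba(model, docs)[, pred]
  }
  exact <- exact %||% (m <= 12)
  phi <- if (m == 1L) {
    v <- value_of(rbind(1, 0))
    v[1] - v[2]
  } else if (exact) {
    shapley_exact(m, value_of)
  } else {
    shapley_kernel_wls(m, value_of, n_samples, seed)
  }
  names(phi) <- words
  explanation(rep_$id, "SHAP", pred, phi, k = k)
}

# Exact Shapley values by enumerating all 2^m coalitions.
shapley_exact <- function(m, value_of) {
  masks <- all_masks(m)
  v <- value_of(masks)
  sizes <- rowSums(masks)
  # weight of a coalition S (not containing j): |S|! (m - |S| - 1)! / m!
  wt <- exp(lfactorial(0:(m - 1)) + lfactorial(m - 1 - 0:(m - 1)) - lfactorial(m))
  # index lookup: mask row index from bit pattern (expand.grid varies col 1 fastest)
  pow <- 2^(seq_len(m) - 1)
  key <- as.integer(masks %*% pow) + 1L
  v_by_key <- numeric(2^m)
  v_by_key[key] <- v
  phi <- numeric(m)
  for (j in seq_len(m)) {
    without_j <- masks[, j] == 0
    s <- sizes[without_j]
    k0 <- key[without_j]
    k1 <- k0 + as.integer(pow[j])
    phi[j] <- sum(wt[s + 1] * (v_by_key[k1] - v_by_key[k0]))
  }
  phi
}

# Kernel SHAP sampling estimator: coalition sizes drawn with probability
# proportional to (m - 1) / (size * (m - size)), members uniform given size;
# solve the least-squares system with v(empty) fixed and the efficiency
# constraint eliminated into the design.
shapley_kernel_wls <- function(m, value_of, n_samples, seed) {
  withr::with_seed(as.integer(seed), {
    sizes <- 1:(m - 1)
    p_size <- (m - 1) / (sizes * (m - sizes))
    p_size <- p_size / sum(p_size)
    drawn <- sample(sizes, n_samples, replace = TRUE, prob = p_size)
    z <- matrix(0L, n_samples, m)
    for (i in seq_len(n_samples)) {
      z[i, sample.int(m, drawn[i])] <- 1L
    }
  })
  ends <- rbind(rep(1, m), rep(0, m))
  v_ends <- value_of(ends)
  v_full <- v_ends[1]
  v0 <- v_ends[2]
  delta <- v_full - v0
  y <- value_of(z)
  a <- z[, -m, drop = FALSE] - z[, m]
  rhs <- y - v0 - z[, m] * delta
  fit <- stats::lm.fit(a, rhs)
  phi <- fit$coefficients
  phi[is.na(phi)] <- 0
  c(phi, delta - sum(phi))
}
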