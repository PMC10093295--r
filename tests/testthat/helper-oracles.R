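# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# Confusion-matrix metrics by explicit counting.
oracle_metrics <- function(y_true, y_pred) {
  prec <- rec <- f1 <- numeric(3)
  for (cl in 1:3) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[cl] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[cl] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[cl] <- if (prec[cl] + rec[cl] > 0) 2 * prec[cl] * rec[cl] / (prec[cl] + rec[cl]) else 0
  }
  list(accuracy = mean(y_true == y_pred), precision = mean(prec),
       recall = mean(rec), f1 = mean(f1), per_class_f1 = f1)
}

# Shapley values by averaging marginal contributions over all m! orderings.
oracle_shapley_permutations <- function(m, value_of_set) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_orders <- perms(seq_len(m))
  phi <- numeric(m)
  for (ord in all_orders) {
    s <- integer()
    v_prev <- value_of_set(s)
    for (j in ord) {
      s <- c(s, j)
      v_now <- value_of_set(s)
      phi[j] <- phi[j] + (v_now - v_prev)
      v_prev <- v_now
    }
  }
  phi / length(all_orders)
}

# Cohen's kappa from the raw contingency table.
oracle_kappa <- function(a, b) {
  lev <- sort(unique(c(a, b)))
  tab <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(a)) {
    tab[as.character(a[i]), as.character(b[i])] <-
      tab[as.character(a[i]), as.character(b[i])] + 1
  }
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Exhaustive-mask LIME oracle: every subset of the report's word types,
# cosine-kernel weights, greedy forward selection with lm(), final weighted
# fit. Returns the selected words' coefficients.
oracle_lime_exact <- function(model, tokens, n_features = 5, sigma = NULL) {
  words <- unique(tokens)
  m <- length(words)
  sigma <- if (is.null(sigma)) 0.25 * sqrt(m) else sigma
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))
  pred <- which.max(predict_proba(model, tokens))
  y <- apply(grid, 1, function(mask) {
    predict_proba(model, tokens[tokens %in% words[mask == 1]])[pred]
  })
  d <- 1 - sqrt(rowSums(grid) / m)
  w <- exp(-d^2 / sigma^2)
  sel <- integer()
  for (step in seq_len(min(n_features, m))) {
    rss <- sapply(setdiff(seq_len(m), sel), function(j) {
      df <- data.frame(y = y, grid[, c(sel, j), drop = FALSE])
      sum(w * stats::lm(y ~ ., data = df, weights = w)$residuals^2)
    })
    cand <- setdiff(seq_len(m), sel)
    sel <- c(sel, cand[which.min(rss)])
  }
  df <- data.frame(y = y, grid[, sel, drop = FALSE])
  fit <- stats::lm(y ~ ., data = df, weights = w)
  stats::setNames(stats::coef(fit)[-1], words[sel])
}
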