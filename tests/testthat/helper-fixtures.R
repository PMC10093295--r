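# Small shared fixtures: corpora are always generated in code at test time.

tok_corpus <- function(tokens, labels, ids = sprintf("t%03d", seq_along(tokens))) {
  tibble::tibble(id = ids, tokens = tokens, label = as.integer(labels))
}

# A planted, perfectly separable tokenized corpus.
separable_corpus <- function(n_per_class = c(6L, 8L, 4L), seed = 11L,
                             n_perhaps_per_class = 0L, p_misspell = 0) {
  cfg <- generator_config(n_per_class = n_per_class, p_valid_inject = 1,
                          n_perhaps_per_class = n_perhaps_per_class,
                          p_misspell = p_misspell, seed = seed)
  g <- generate_corpus(cfg)
  list(tok = tokenize_corpus(g$corpus, stopwords = character()),
       lexicon = g$lexicon)
}

# Additive toy model: P(class 1 | S) = base + sum of contributions of the
# word types present; the remaining mass is split 60/40 over classes 2/3.
additive_model <- function(contrib, base = 0.2) {
  function_classifier(function(tokens) {
    p1 <- base + sum(contrib[names(contrib) %in% tokens])
    p1 <- min(max(p1, 1e-6), 1 - 1e-6)
    c(p1, 0.6 * (1 - p1), 0.4 * (1 - p1))
  })
}

# Non-additive toy model: like additive_model but with pairwise interaction
# bonuses for co-present word pairs, so sampled explainers have genuine
# estimation error.
interactive_model <- function(contrib, pairs, base = 0.3) {
  function_classifier(function(tokens) {
    p1 <- base + sum(contrib[names(contrib) %in% tokens])
    for (pr in pairs) {
      if (all(pr$words %in% tokens)) p1 <- p1 + pr$w
    }
    p1 <- min(max(p1, 1e-6), 1 - 1e-6)
    c(p1, 0.6 * (1 - p1), 0.4 * (1 - p1))
  })
}

# Single-determinant toy model: class 1 is driven by one word.
determinant_model <- function(word = "wstar") {
  function_classifier(function(tokens) {
    if (word %in% tokens) c(0.9, 0.05, 0.05) else c(0.1, 0.45, 0.45)
  })
}

random_label_pair <- function(n, seed) {
  withr::with_seed(seed, list(
    y_true = sample(1:3, n, replace = TRUE),
    y_pred = sample(1:3, n, replace = TRUE)
  ))
}
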