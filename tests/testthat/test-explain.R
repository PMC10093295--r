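test_that("top_k_words ranks by magnitude with lexicographic tie-breaks", {
  s <- c(a = 0.3, b = -0.4, c = 0.1)
  got <- top_k_words(s, 2)
  expect_identical(got$word, c("b", "a"))
  expect_equal(got$score, c(-0.4, 0.3))
  ties <- top_k_words(c(zz = 0.2, aa = -0.2, mm = 0.2), 3)
  expect_identical(ties$word, c("aa", "mm", "zz"))
  expect_identical(nrow(top_k_words(s, 10)), 3L)
})

test_that("LIME finds a single determinant word and is deterministic", {
  model <- determinant_model("wstar")
  report <- c("wstar", "ruis", "meer", "ruis", "iets")
  e <- lime_explain(model, report, n_samples = 400, seed = 5)
  expect_identical(e$method, "LIME")
  expect_identical(e$predicted_class, 1L)
  expect_identical(e$items$word[1], "wstar")
  expect_gt(e$items$score[1], 0)
  e2 <- lime_explain(model, report, n_samples = 400, seed = 5)
  expect_equal(e$items, e2$items)
  expect_error(lime_explain(model, character()), "empty report")
  expect_error(lime_explain(model, report, n_samples = 10), "at least 50")
})

test_that("sampled LIME matches the exhaustive-mask oracle on a small report", {
  contrib <- c(aa = 0.25, bb = 0.15, cc = -0.1, dd = 0.05,
               ee = 0.02, ff = -0.02, gg = 0.01, hh = 0.005)
  model <- additive_model(contrib, base = 0.45)
  report <- names(contrib)
  want <- oracle_lime_exact(model, report)
  got_exact <- lime_explain(model, report, exact = TRUE)
  for (w in got_exact$items$word) {
    expect_equal(got_exact$attributions[[w]], unname(want[w]), tolerance = 1e-8)
  }
  got <- lime_explain(model, report, n_samples = 4096, seed = 17)
  common <- intersect(got$items$word, names(want))
  expect_gte(length(common), 4)
  for (w in common) {
    expect_lt(abs(got$attributions[[w]] - want[w]), 0.05)
  }
})

test_that("Kernel SHAP satisfies the Shapley axioms and matches brute-force enumeration", {
  contrib <- c(aa = 0.2, bb = 0.12, cc = -0.08, dd = 0.05, ee = 0.03, ff = 0.01)
  model <- additive_model(contrib, base = 0.4)
  report <- names(contrib)
  e <- kernel_shap_explain(model, report, exact = TRUE, k = 6)
  # additivity: Shapley value of an additive game is the per-word contribution
  expect_equal(unname(e$attributions[report]), unname(contrib), tolerance = 1e-9)
  # efficiency: attributions sum to v(full) - v(empty)
  v_full <- predict_proba(model, report)[1]
  v0 <- predict_proba(model, character())[1]
  expect_lt(abs(sum(e$attributions) - (v_full - v0)), 1e-6)
  # exact mode agrees with an independent all-permutations oracle
  value_of_set <- function(s) {
    predict_proba(model, report[report %in% report[s]])[1]
  }
  want <- oracle_shapley_permutations(6, value_of_set)
  expect_equal(unname(e$attributions[report]), want, tolerance = 1e-9)
})

test_that("sampled Kernel SHAP converges to the exact solution", {
  contrib <- c(aa = 0.2, bb = 0.12, cc = -0.08, dd = 0.05,
               ee = 0.03, ff = 0.01, gg = -0.01, hh = 0.02)
  pairs <- list(list(words = c("aa", "bb"), w = 0.1),
                list(words = c("cc", "dd"), w = -0.06),
                list(words = c("ee", "hh"), w = 0.05))
  model <- interactive_model(contrib, pairs, base = 0.35)
  report <- names(contrib)
  exact <- kernel_shap_explain(model, report, exact = TRUE, k = 8)$attributions
  got <- kernel_shap_explain(model, report, n_samples = 4096, seed = 3,
                             exact = FALSE, k = 8)$attributions
  expect_lt(max(abs(got[report] - exact[report])), 0.02)
})

test_that("sampled LIME and SHAP errors shrink with the sampling budget", {
  contrib <- c(aa = 0.22, bb = 0.12, cc = -0.09, dd = 0.05,
               ee = 0.03, ff = -0.02, gg = 0.01, hh = 0.005)
  pairs <- list(list(words = c("aa", "cc"), w = 0.09),
                list(words = c("bb", "dd"), w = -0.05),
                list(words = c("ff", "gg"), w = 0.04))
  model <- interactive_model(contrib, pairs, base = 0.4)
  report <- names(contrib)
  shap_exact <- kernel_shap_explain(model, report, exact = TRUE, k = 8)$attributions
  lime_exact <- lime_explain(model, report, exact = TRUE)$attributions
  budgets <- c(128, 512, 4096)
  err_shap <- err_lime <- numeric(3)
  n_seeds <- 6
  for (b in seq_along(budgets)) {
    es <- el <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      got_s <- kernel_shap_explain(model, report, n_samples = budgets[b],
                                   seed = 100 + s, exact = FALSE, k = 8)$attributions
      es[s] <- max(abs(got_s[report] - shap_exact[report]))
      got_l <- lime_explain(model, report, n_samples = max(budgets[b], 50),
                            seed = 100 + s)$attributions
      common <- intersect(names(got_l), names(lime_exact))
      el[s] <- max(abs(got_l[common] - lime_exact[common]))
    }
    err_shap[b] <- mean(es)
    err_lime[b] <- mean(el)
  }
  expect_true(all(diff(err_shap) < 0))
  expect_true(all(diff(err_lime) < 0))
})

test_that("integrated gradients is exact for linear functions and zero at the baseline", {
  w <- c(0.5, -1.2, 2, 0)
  x <- c(1, 2, -1, 3)
  for (steps in c(2, 7, 50)) {
    ig <- ig_attribute(x, baseline = NULL, gradient = function(z) w,
                       n_steps = steps)
    expect_equal(ig, x * w)
  }
  x0 <- c(1, 1, 1, 1)
  expect_equal(ig_attribute(x0, baseline = x0, gradient = function(z) w,
                            n_steps = 8), rep(0, 4))
})

test_that("IG on the embedding-bag network satisfies completeness", {
  sep <- separable_corpus(c(5, 7, 3), seed = 23)
  clf <- embedding_bag_classifier(oversample(sep$tok, 1), seed = 4, epochs = 150)
  dm <- as_differentiable(clf)
  toks <- sep$tok$tokens[[1]]
  x <- dm$embed(toks)
  p_full <- dm$forward(x)
  cl <- which.max(p_full)
  p0 <- dm$forward(x * 0)
  ig <- ig_attribute(x, baseline = NULL,
                     gradient = function(z) dm$gradient(z, cl), n_steps = 2000)
  expect_lt(abs(sum(ig) - (p_full[cl] - p0[cl])), 1e-3)
  # word-level explanation aggregates occurrences of a type by summation
  e <- integrated_gradients_explain(dm, toks, n_steps = 200)
  expect_identical(e$method, "IG")
  expect_setequal(names(e$attributions), unique(toks))
})

test_that("differentiable wrappers reproduce their classifier's probabilities", {
  sep <- separable_corpus(c(4, 6, 3), seed = 13)
  toks <- sep$tok$tokens[[2]]
  lr <- tfidf_logistic_classifier(sep$tok)
  dm_lr <- as_differentiable(lr)
  expect_equal(unname(dm_lr$forward(dm_lr$embed(toks))),
               unname(predict_proba(lr, toks)), tolerance = 1e-9)
  eb <- embedding_bag_classifier(sep$tok, seed = 2, epochs = 50)
  dm_eb <- as_differentiable(eb)
  expect_equal(unname(dm_eb$forward(dm_eb$embed(toks))),
               unname(predict_proba(eb, toks)), tolerance = 1e-9)
  # analytic logistic gradient agrees with a numerical derivative
  x <- dm_lr$embed(toks)
  g <- dm_lr$gradient(x, 1)
  j <- which.max(abs(x))
  h <- 1e-6
  xp <- x; xp[j] <- xp[j] + h
  xm <- x; xm[j] <- xm[j] - h
  num <- (dm_lr$forward(xp)[1] - dm_lr$forward(xm)[1]) / (2 * h)
  expect_equal(g[j], unname(num), tolerance = 1e-5)
  expect_error(integrated_gradients_explain(lr, toks), "differentiable-model")
})

test_that("explainers see only the model, never the true label", {
  expect_false("label" %in% names(formals(lime_explain)))
  expect_false("label" %in% names(formals(kernel_shap_explain)))
  expect_false("label" %in% names(formals(integrated_gradients_explain)))
})
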