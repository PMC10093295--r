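test_that("oversampling equalizes class counts without deleting originals", {
  toks <- replicate(12, c("aa", "bb"), simplify = FALSE)
  corpus <- tok_corpus(toks, rep(1:3, c(4, 6, 2)))
  over <- oversample(corpus, seed = 3)
  expect_identical(as.integer(table(factor(over$label, 1:3))), c(6L, 6L, 6L))
  expect_true(all(corpus$id %in% over$id))
  expect_identical(oversample(corpus, seed = 3), oversample(corpus, seed = 3))
  # scheme of the study's class counts: (271, 531, 21) -> (531, 531, 531)
  big <- tok_corpus(replicate(823, "aa", simplify = FALSE), rep(1:3, c(271, 531, 21)))
  expect_identical(as.integer(table(oversample(big, 1)$label)), c(531L, 531L, 531L))
  # balanced and single-class corpora come back unchanged
  bal <- tok_corpus(toks[1:4], c(1, 1, 2, 2))
  expect_identical(oversample(bal, 1), bal)
  mono <- tok_corpus(toks[1:3], c(2, 2, 2))
  expect_identical(oversample(mono, 1), mono)
  expect_error(oversample(bal[0, ], 1), "empty")
})

test_that("majority classifier predicts the most frequent class with prior probabilities", {
  corpus <- tok_corpus(replicate(3, "aa", simplify = FALSE), c(1, 2, 2))
  m <- majority_classifier(corpus)
  expect_identical(predict_class(m, c("whatever")), 2L)
  expect_equal(unname(predict_proba(m, "x")), c(1 / 3, 2 / 3, 0))
  # tie breaks to the lowest class id
  tie <- majority_classifier(tok_corpus(replicate(4, "aa", simplify = FALSE),
                                        c(2, 2, 3, 3)))
  expect_identical(predict_class(tie, "x"), 2L)
})

test_that("logistic regression: priors for null features, sign recovery, separable fit", {
  # zero features -> intercept-only fit reproduces class priors
  fit0 <- fit_logistic(matrix(0, 10, 2), rep(c(1, 2), c(3, 7)), l2_strength = 0)
  expect_equal(unname(logistic_proba(fit0, c(0, 0))), c(0.3, 0.7, 0), tolerance = 1e-5)

  # single informative binary feature: sign matches class association,
  # checked against a brute-force penalized-likelihood grid
  x <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0), ncol = 1)
  y <- rep(c(2, 1), c(4, 6))
  fit1 <- fit_logistic(x, y, l2_strength = 0.01)
  w_feature <- fit1$coef[2, 2] - fit1$coef[1, 2]
  grid <- expand.grid(b = seq(-4, 4, 0.1), w = seq(-6, 6, 0.1))
  ll <- mapply(function(b, w) {
    eta <- b + w * x[, 1]
    sum(ifelse(y == 2, eta, 0) - log1p(exp(eta))) - 0.01 * (b^2 + w^2)
  }, grid$b, grid$w)
  best <- grid[which.max(ll), ]
  expect_gt(w_feature, 0)
  expect_gt(best$w, 0)
  expect_equal(sign(w_feature), sign(best$w))

  # planted separable corpus is fit to training accuracy 1 when the ridge
  # penalty is weak enough not to bind
  sep <- separable_corpus(c(6, 8, 4))
  clf <- tfidf_logistic_classifier(sep$tok, l2_strength = 1e-3)
  expect_equal(mean(predict_class(clf, sep$tok$tokens) == sep$tok$label), 1.0)
  expect_true(clf$model$converged)
  expect_error(fit_logistic(matrix(0, 3, 1), c(2, 2, 2)), "two classes")
})

test_that("metrics reproduce the majority-baseline row from the study's class counts", {
  y_true <- rep(1:3, c(271, 531, 21))
  res <- compute_metrics(y_true, rep(2L, 823))
  expect_equal(round(res$accuracy, 2), 0.65)
  expect_equal(round(res$precision, 2), 0.22)
  expect_equal(round(res$recall, 2), 0.33)
  expect_equal(round(res$f1, 2), 0.26)
  expect_identical(sum(res$confusion), 823L)
})

test_that("metrics match hand counts and a brute-force oracle on random labelings", {
  perfect <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall, perfect$f1),
               rep(1, 4))

  res <- compute_metrics(c(1, 2, 3, 1), c(1, 2, 1, 2))
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$per_class$precision, c(1 / 2, 1 / 2, 0))
  expect_equal(res$per_class$recall, c(1 / 2, 1, 0))
  expect_equal(res$precision, 1 / 3)
  expect_equal(res$recall, 0.5)
  expect_equal(res$f1, (0.5 + 2 / 3) / 3)

  for (case in 1:300) {
    yy <- random_label_pair(n = sample(3:40, 1), seed = 1000 + case)
    got <- compute_metrics(yy$y_true, yy$y_pred)
    want <- oracle_metrics(yy$y_true, yy$y_pred)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f1, want$f1)
    # identities: macro F1 bounded by best per-class F1; trace ratio accuracy
    expect_lte(got$f1, max(want$per_class_f1) + 1e-12)
    expect_equal(got$accuracy, sum(diag(got$confusion)) / sum(got$confusion))
  }
  expect_error(compute_metrics(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("leave-one-out evaluation is deterministic and perfect on separable data", {
  sep <- separable_corpus(c(20, 30, 10))
  factory <- function(corpus, seed) tfidf_logistic_classifier(corpus, seed = seed)
  res <- loo_evaluate(sep$tok, factory, seed = 21)
  expect_equal(res$accuracy, 1.0)
  res2 <- loo_evaluate(sep$tok, factory, seed = 21)
  expect_identical(res$confusion, res2$confusion)
  expect_identical(res$y_pred, res2$y_pred)
  expect_error(loo_evaluate(sep$tok[1, ], factory), "at least 2")
})

test_that("majority classifier inside LOO misclassifies every minority report", {
  # with in-fold oversampling the training classes balance, so ties break
  # to the lowest id: minority class 3 can never be predicted
  corpus <- tok_corpus(replicate(5, "aa", simplify = FALSE), c(2, 2, 2, 3, 3))
  res <- loo_evaluate(corpus, function(corpus, seed) majority_classifier(corpus),
                      seed = 1)
  expect_identical(res$y_pred[res$y_true == 3], c(2L, 2L))
  expect_identical(res$y_pred[res$y_true == 2], c(2L, 2L, 2L))
})

test_that("hold-out evaluation uses weighted metrics and enforces disjoint ids", {
  cfg <- generator_config(n_per_class = c(8, 10, 4), p_valid_inject = 1,
                          n_perhaps_per_class = 0, p_misspell = 0, seed = 31)
  g <- generate_corpus(cfg)
  tok <- tokenize_corpus(g$corpus, character())
  test_idx <- c(1, 2, 9, 10, 19)
  factory <- function(corpus, seed) tfidf_logistic_classifier(corpus, seed = seed)
  res <- holdout_evaluate(tok[-test_idx, ], tok[test_idx, ], factory, seed = 2)
  expect_equal(res$accuracy, 1.0)
  expect_identical(res$average, "weighted")

  # single-class test set, all correct -> weighted P = R = F1 = 1
  one_cl <- which(tok$label == 2)[1:3]
  res1 <- holdout_evaluate(tok[-one_cl, ], tok[one_cl, ], factory, seed = 2)
  expect_equal(c(res1$precision, res1$recall, res1$f1), rep(1, 3))

  expect_error(holdout_evaluate(tok, tok[1:2, ], factory), "disjoint")
  expect_error(holdout_evaluate(tok, tok[0, ], factory), "empty test set")
})
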