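#' Construct a domain lexicon
#'
#' Expert word lists used for alignment scoring: per-class valid and
#' perhaps-valid words, a global wrong-word (spurious feature) list, and a
#' surface-form-to-canonical normalization map (the mechanized equivalent
#' of manually correcting misspellings and resolving synonyms before
#' lookup). Within a class, valid and perhaps-valid must be disjoint; the
#' wrong list must be disjoint from every valid list.
#'
#' @param valid,perhaps_valid Named lists (`"1"`,`"2"`,`"3"`) of character
#'   vectors.
#' @param wrong Character vector.
#' @param normalization_map Named list/vector: surface form -> canonical.
#' @return An object of class `domain_lexicon`.
#' @export
domain_lexicon <- function(valid, perhaps_valid, wrong = character(),
                           normalization_map = list()) {
  for (cl in names(valid)) {
    if (length(intersect(valid[[cl]], perhaps_valid[[cl]] %||% character()))) {
      stop("valid and perhaps_valid overlap within class ", cl, call. = FALSE)
    }
    if (length(intersect(valid[[cl]], wrong))) {
      stop("wrong list overlaps valid list of class ", cl, call. = FALSE)
    }
  }
  structure(list(valid = valid, perhaps_valid = perhaps_valid,
                 wrong = wrong, normalization_map = as.list(normalization_map)),
            class = "domain_lexicon")
}

#' Use a synthetic lexicon as the expert reference
#'
#' The generator's ground-truth word roles double as a domain lexicon
#' (filler words become "unknown" at categorization time).
#'
#' @param lexicon A `synthetic_lexicon`.
#' @return A [domain_lexicon()].
#' @export
as_domain_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, c("synthetic_lexicon", "domain_lexicon")))
  if (inherits(lexicon, "domain_lexicon")) return(lexicon)
  domain_lexicon(valid = lexicon$valid, perhaps_valid = lexicon$perhaps_valid,
                 wrong = lexicon$wrong,
                 normalization_map = lexicon$normalization_map)
}

#' Reduce a report to, or strip it of, its important words
#'
#' `mode = "only"` keeps every occurrence of the important word types in
#' original order; `mode = "without"` removes every occurrence. The two
#' outputs partition the original token multiset.
#'
#' @param tokens Character token vector.
#' @param important_words Character vector of word types.
#' @param mode `"only"` or `"without"`.
#' @return Character token vector (possibly empty).
#' @export
reduce_report <- function(tokens, important_words, mode = c("only", "without")) {
  mode <- match.arg(mode)
  keep <- tokens %in% important_words
  if (mode == "only") tokens[keep] else tokens[!keep]
}

#' Normalize importance scores to weights summing to one
#'
#' Converts signed importance scores to nonnegative shares:
#' `weight_i = |s_i| / sum_j |s_j|`. If every score is zero the weights
#' are uniform.
#'
#' @param items Data frame with columns `word`, `score`, or a named numeric
#'   vector.
#' @return Data frame with columns `word`, `weight`; weights sum to 1.
#' @export
normalize_scores <- function(items) {
  if (is.numeric(items)) {
    items <- data.frame(word = names(items), score = as.numeric(items),
                        stringsAsFactors = FALSE)
  }
  stopifnot(nrow(items) > 0)
  s <- abs(items$score)
  tot <- sum(s)
  w <- if (tot > 0) s / tot else rep(1 / length(s), length(s))
  data.frame(word = items$word, weight = w, stringsAsFactors = FALSE)
}

audit_categories <- c("valid", "perhaps_valid", "unknown",
                      "invalid_other", "invalid_wrong")

#' Categorize an explanation word against the expert lexicon
#'
#' The word is first canonicalized through the lexicon's normalization map,
#' then assigned by precedence: in the predicted class's valid list ->
#' `valid`; in its perhaps-valid list -> `perhaps_valid`; in the global
#' wrong list -> `invalid_wrong`; in the valid/perhaps-valid list of a
#' different class only -> `invalid_other`; otherwise `unknown`. Every word
#' maps to exactly one category.
#'
#' @param word A single word.
#' @param predicted_class Class id in `{1, 2, 3}`.
#' @param lexicon A [domain_lexicon()] (or `synthetic_lexicon`).
#' @return One of `"valid"`, `"perhaps_valid"`, `"unknown"`,
#'   `"invalid_other"`, `"invalid_wrong"`.
#' @export
categorize_word <- function(word, predicted_class, lexicon) {
  stopifnot(predicted_class %in% 1:3)
  w <- lexicon$normalization_map[[word]] %||% word
  cl <- as.character(predicted_class)
  if (w %in% (lexicon$valid[[cl]] %||% character())) return("valid")
  if (w %in% (lexicon$perhaps_valid[[cl]] %||% character())) return("perhaps_valid")
  if (w %in% lexicon$wrong) return("invalid_wrong")
  others <- setdiff(as.character(1:3), cl)
  other_words <- unlist(c(lexicon$valid[others], lexicon$perhaps_valid[others]),
                        use.names = FALSE)
  if (w %in% other_words) return("invalid_other")
  "unknown"
}

#' Score explanation-to-expert alignment
#'
#' For each explanation: normalize the top-k importance scores to weights
#' summing to 1, canonicalize each word, categorize it against the
#' explanation's predicted class, and sum the weights per category. The
#' summary reports, per method and category, the mean and standard
#' deviation of those sums over reports. The five category sums are
#' conserved: they total 1 for every report.
#'
#' @param explanations List of [explanation()] objects (any mix of
#'   methods).
#' @param lexicon A [domain_lexicon()] or `synthetic_lexicon`.
#' @return An object of class `alignment_summary`: a tibble with columns
#'   `method`, `category`, `mean`, `sd`, plus a `per_report` attribute (one
#'   row per explanation with the five category sums).
#' @export
alignment_scores <- function(explanations, lexicon) {
  stopifnot(length(explanations) > 0)
  lexicon <- as_domain_lexicon(lexicon)
  rows <- lapply(explanations, function(e) {
    stopifnot(inherits(e, "explanation"))
    wts <- normalize_scores(e$items)
    cats <- vapply(wts$word, categorize_word, character(1),
                   predicted_class = e$predicted_class, lexicon = lexicon)
    sums <- vapply(audit_categories,
                   function(cat) sum(wts$weight[cats == cat]), numeric(1))
    c(list(report_id = e$report_id, method = e$method), as.list(sums))
  })
  per_report <- do.call(rbind, lapply(rows, function(r) {
    tibble::as_tibble(r)
  }))
  summary <- do.call(rbind, lapply(split(per_report, per_report$method),
    function(d) {
      tibble::tibble(
        method = d$method[1],
        category = audit_categories,
        mean = unname(vapply(audit_categories, function(cat) mean(d[[cat]]), numeric(1))),
        sd = unname(vapply(audit_categories, function(cat) stats::sd(d[[cat]]), numeric(1)))
      )
    }))
  rownames(summary) <- NULL
  structure(summary, per_report = per_report, class = c("alignment_summary",
                                                        class(summary)))
}

#' Fidelity and deletion check of explanations
#'
#' Within the same leave-one-out protocol as [loo_evaluate()], each
#' held-out report is predicted three times by its fold's freshly trained
#' model: in full, reduced to only its important words (fidelity), and
#' stripped of them (deletion check). Accuracies are aggregated per
#' explanation method; `acc_full` is by construction identical across
#' methods. Sufficient explanations keep `acc_only` near `acc_full`;
#' necessary explanations push `acc_without` down.
#'
#' @param corpus Tokenized corpus tibble.
#' @param classifier_factory Function(corpus, seed) -> adapter.
#' @param explanations List of [explanation()] objects covering every
#'   corpus report for every method present.
#' @param seed Master seed (same fold derivation as [loo_evaluate()]).
#' @return An object of class `fidelity_report`: tibble with columns
#'   `method`, `acc_full`, `acc_only_important`, `acc_without_important`.
#' @export
fidelity_deletion_check <- function(corpus, classifier_factory, explanations,
                                    seed = 1L) {
  n <- nrow(corpus)
  methods <- unique(vapply(explanations, `[[`, character(1), "method"))
  imp <- list()
  for (e in explanations) {
    imp[[e$method]][[e$report_id]] <- e$items$word
  }
  for (m in methods) {
    missing <- setdiff(corpus$id, names(imp[[m]]))
    if (length(missing)) {
      stop(sprintf("missing %s explanation for report(s): %s",
                   m, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  correct_full <- logical(n)
  correct_only <- matrix(FALSE, n, length(methods), dimnames = list(NULL, methods))
  correct_without <- correct_only
  for (i in seq_len(n)) {
    fs <- loo_fold_seed(seed, i)
    train <- oversample(corpus[-i, , drop = FALSE], seed = fs)
    model <- classifier_factory(train, seed = fs)
    toks <- corpus$tokens[[i]]
    truth <- corpus$label[i]
    correct_full[i] <- predict_class(model, toks) == truth
    for (m in methods) {
      words <- imp[[m]][[corpus$id[i]]]
      correct_only[i, m] <-
        predict_class(model, reduce_report(toks, words, "only")) == truth
      correct_without[i, m] <-
        predict_class(model, reduce_report(toks, words, "without")) == truth
    }
  }
  out <- tibble::tibble(
    method = methods,
    acc_full = mean(correct_full),
    acc_only_important = colMeans(correct_only)[methods],
    acc_without_important = colMeans(correct_without)[methods]
  )
  structure(out, class = c("fidelity_report", class(out)))
}

#' Cohen's kappa for two labelings
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with `p_o` the
#' observed agreement and `p_e` the chance agreement implied by the two
#' marginal label distributions. When `p_e = 1` (both raters constant on
#' the same label set), kappa is defined as 1 for perfect agreement and 0
#' otherwise.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences must have equal length", call. = FALSE)
  }
  stopifnot(length(labels_a) > 0)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / length(a)) * (table(b) / length(b)))
  if (isTRUE(all.equal(p_e, 1))) {
    return(if (isTRUE(all.equal(p_o, 1))) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}
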