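#' Configuration for the synthetic report generator
#'
#' Describes a synthetic corpus of labeled free-text reports over three
#' classes (1 = Diagnosis, 2 = Progression, 3 = Monitoring). The defaults
#' emulate the class imbalance of a retrospective MS radiology dataset
#' (271 / 531 / 21 reports) and its vocabulary structure: per-class
#' label-determining ("valid") words, context-dependent ("perhaps valid")
#' words injected mostly but not exclusively into their own class, globally
#' spurious ("wrong") words injected label-independently, and neutral filler.
#'
#' @param n_per_class Integer vector of length 3: number of reports per class.
#' @param n_total Optional single integer; if given, `n_per_class` is derived
#'   by largest-remainder apportionment of the 271:531:21 ratio (see
#'   [apportion_counts()]).
#' @param report_length_range Integer pair `(min, max)` tokens per report;
#'   `min` must be at least 5.
#' @param n_valid_per_class,n_perhaps_per_class Number of valid and
#'   perhaps-valid word types per class.
#' @param n_wrong,n_filler Number of spurious and filler word types.
#' @param p_valid_inject Probability that a class-c report contains each
#'   class-c valid word. Valid words of other classes are never injected.
#' @param p_perhaps_inject Probability that a report contains each
#'   perhaps-valid word of its own class.
#' @param p_perhaps_other Probability that a report contains each
#'   perhaps-valid word of another class (context dependence is modeled as
#'   an elevated own-class rate versus a reduced other-class rate).
#' @param p_wrong_inject Probability that any report contains each wrong
#'   word, identical across classes (spuriousness).
#' @param p_misspell Probability that a planted word surfaces in its
#'   corrupted (single-character-deletion) form; the corruption is recorded
#'   in the lexicon's `normalization_map`.
#' @param seed Integer seed; identical config and seed give a byte-identical
#'   corpus.
#' @return An object of class `generator_config` (a named list).
#' @export
generator_config <- function(n_per_class = c(271L, 531L, 21L),
                             n_total = NULL,
                             report_length_range = c(20L, 60L),
                             n_valid_per_class = 5L,
                             n_perhaps_per_class = 3L,
                             n_wrong = 5L,
                             n_filler = 60L,
                             p_valid_inject = 0.7,
                             p_perhaps_inject = 0.5,
                             p_perhaps_other = p_perhaps_inject / 4,
                             p_wrong_inject = 0.8,
                             p_misspell = 0.1,
                             seed = 1L) {
  if (!is.null(n_total)) {
    n_per_class <- apportion_counts(n_total, c(271, 531, 21))
  }
  n_per_class <- as.integer(n_per_class)
  if (length(n_per_class) != 3L || anyNA(n_per_class) || any(n_per_class < 0)) {
    stop("`n_per_class` must be three nonnegative integers", call. = FALSE)
  }
  if (sum(n_per_class) == 0L) {
    stop("configuration error: total number of reports is zero", call. = FALSE)
  }
  report_length_range <- as.integer(report_length_range)
  if (length(report_length_range) != 2L ||
      report_length_range[1] < 5L ||
      report_length_range[2] < report_length_range[1]) {
    stop("`report_length_range` must be (min, max) with min >= 5", call. = FALSE)
  }
  for (nm in c("p_valid_inject", "p_perhaps_inject", "p_perhaps_other",
               "p_wrong_inject", "p_misspell")) {
    assert_prob(get(nm), nm)
  }
  cfg <- list(
    n_per_class = n_per_class,
    report_length_range = report_length_range,
    n_valid_per_class = as.integer(n_valid_per_class),
    n_perhaps_per_class = as.integer(n_perhaps_per_class),
    n_wrong = as.integer(n_wrong),
    n_filler = as.integer(n_filler),
    p_valid_inject = p_valid_inject,
    p_perhaps_inject = p_perhaps_inject,
    p_perhaps_other = p_perhaps_other,
    p_wrong_inject = p_wrong_inject,
    p_misspell = p_misspell,
    seed = as.integer(seed)
  )
  if (cfg$n_valid_per_class < 1L) {
    stop("`n_valid_per_class` must be at least 1", call. = FALSE)
  }
  if (cfg$n_filler < 1L) {
    stop("`n_filler` must be at least 1", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Largest-remainder apportionment of a total over integer weights
#'
#' Splits `total` into integer counts proportional to `weights`, assigning
#' leftover units to the largest fractional remainders (ties go to the
#' earlier index). Used to reproduce the 271:531:21 class imbalance at any
#' corpus size.
#'
#' @param total Single nonnegative integer.
#' @param weights Positive numeric weights.
#' @return Integer vector of the same length as `weights`, summing to `total`.
#' @export
apportion_counts <- function(total, weights) {
  stopifnot(total >= 0, all(weights > 0))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    rem <- quota - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Deterministic pseudo-word inventory: role prefix + class letter + fixed
# width base-26 code. All letters, length >= 5, so every word survives
# preprocessing and role sets are disjoint by construction.
make_words <- function(n, prefix) {
  if (n == 0L) return(character())
  code <- vapply(seq_len(n) - 1L, function(i) {
    paste0(letters[(i %/% 676) %% 26 + 1],
           letters[(i %/% 26) %% 26 + 1],
           letters[i %% 26 + 1])
  }, character(1))
  paste0(prefix, code)
}

# Single-character deletion keyed by the active RNG stream; returns NA when
# no deletion position yields a form unseen so far.
corrupt_word <- function(word, taken) {
  pos <- sample.int(nchar(word), nchar(word))
  for (p in pos) {
    cand <- paste0(substr(word, 1, p - 1), substr(word, p + 1, nchar(word)))
    if (nchar(cand) >= 2 && !(cand %in% taken)) return(cand)
  }
  NA_character_
}

build_lexicon <- function(cfg) {
  clet <- c("d", "p", "m")
  valid <- lapply(1:3, function(c) make_words(cfg$n_valid_per_class, paste0("val", clet[c])))
  perhaps <- lapply(1:3, function(c) make_words(cfg$n_perhaps_per_class, paste0("per", clet[c])))
  names(valid) <- names(perhaps) <- as.character(1:3)
  wrong <- make_words(cfg$n_wrong, "spur")
  filler <- make_words(cfg$n_filler, "fil")
  canon <- c(unlist(valid), unlist(perhaps), wrong, filler)
  plantable <- c(unlist(valid), unlist(perhaps), wrong)
  nmap <- character()
  taken <- canon
  for (w in plantable) {
    cw <- corrupt_word(w, taken)
    if (!is.na(cw)) {
      nmap[cw] <- w
      taken <- c(taken, cw)
    }
  }
  synthetic_lexicon(valid = valid, perhaps_valid = perhaps, wrong = wrong,
                    filler = filler, normalization_map = as.list(nmap))
}

#' Construct a synthetic lexicon
#'
#' The ground-truth word-role inventory of a generated corpus: per-class
#' valid and perhaps-valid word lists, a global wrong-word (spurious) list,
#' filler words, and a map from corrupted surface forms back to canonical
#' words. Role sets must be pairwise disjoint and every normalization-map
#' key must resolve to a word appearing in exactly one role set.
#'
#' @param valid,perhaps_valid Named lists (`"1"`,`"2"`,`"3"`) of character
#'   vectors.
#' @param wrong,filler Character vectors.
#' @param normalization_map Named list or character vector mapping corrupted
#'   form to canonical word.
#' @return An object of class `synthetic_lexicon`.
#' @export
synthetic_lexicon <- function(valid, perhaps_valid, wrong, filler,
                              normalization_map = list()) {
  lex <- structure(
    list(valid = valid, perhaps_valid = perhaps_valid, wrong = wrong,
         filler = filler,
         normalization_map = as.list(normalization_map)),
    class = "synthetic_lexicon"
  )
  roles <- list(class_lists = unique(c(unlist(valid), unlist(perhaps_valid))),
                wrong = unique(wrong), filler = unique(filler))
  for (i in seq_along(roles)) {
    for (j in seq_along(roles)) {
      if (i < j && length(intersect(roles[[i]], roles[[j]]))) {
        stop("configuration error: lexicon role sets are not disjoint",
             call. = FALSE)
      }
    }
  }
  all_words <- unlist(roles, use.names = FALSE)
  targets <- unlist(lex$normalization_map, use.names = FALSE)
  if (length(targets) && !all(targets %in% all_words)) {
    stop("normalization_map values must be lexicon words", call. = FALSE)
  }
  lex
}

#' Generate a labeled synthetic report corpus
#'
#' Draws a corpus whose statistical structure matches the audit's
#' assumptions: exact per-class counts, class-c valid words planted only in
#' class-c reports, perhaps-valid words planted with an elevated own-class
#' rate, wrong words planted label-independently, misspellings recorded in
#' the lexicon, filler completing each report to its sampled length. Raw
#' text is rendered as capitalized, period-delimited pseudo-sentences so
#' that preprocessing is exercised.
#'
#' @param config A [generator_config()].
#' @return A list with `corpus` (tibble: `id`, `text`, `label`) and
#'   `lexicon` (a `synthetic_lexicon`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    lex <- build_lexicon(config)
    nmap_rev <- unlist(lex$normalization_map) # corrupted -> canonical
    corrupt_of <- stats::setNames(names(nmap_rev), nmap_rev) # canonical -> corrupted
    n_total <- sum(config$n_per_class)
    ids <- sprintf("r%04d", seq_len(n_total))
    labels <- rep.int(1:3, config$n_per_class)
    texts <- character(n_total)
    for (i in seq_len(n_total)) {
      cl <- labels[i]
      len <- sample(seq(config$report_length_range[1],
                        config$report_length_range[2]), 1L)
      planted <- character()
      vw <- lex$valid[[cl]]
      planted <- c(planted, vw[stats::runif(length(vw)) < config$p_valid_inject])
      for (c2 in 1:3) {
        pw <- lex$perhaps_valid[[c2]]
        p <- if (c2 == cl) config$p_perhaps_inject else config$p_perhaps_other
        planted <- c(planted, pw[stats::runif(length(pw)) < p])
      }
      planted <- c(planted,
                   lex$wrong[stats::runif(length(lex$wrong)) < config$p_wrong_inject])
      if (length(planted)) {
        flip <- stats::runif(length(planted)) < config$p_misspell
        has_form <- planted %in% names(corrupt_of)
        planted[flip & has_form] <- corrupt_of[planted[flip & has_form]]
      }
      n_fill <- max(0L, len - length(planted))
      toks <- c(planted, sample(lex$filler, n_fill, replace = TRUE))
      toks <- sample(toks, length(toks))
      texts[i] <- render_text(toks)
    }
    list(corpus = tibble::tibble(id = ids, text = texts, label = labels),
         lexicon = lex)
  })
}

# Join tokens into pseudo-sentences of 8-14 words, capitalized and
# period-terminated, so the raw text needs genuine normalization.
render_text <- function(tokens) {
  n <- length(tokens)
  if (n == 0L) return("Leeg.")
  sentences <- character()
  i <- 1L
  while (i <= n) {
    k <- min(n - i + 1L, sample(8:14, 1L))
    chunk <- tokens[i:(i + k - 1L)]
    substr(chunk[1], 1, 1) <- toupper(substr(chunk[1], 1, 1))
    sentences <- c(sentences, paste0(paste(chunk, collapse = " "), "."))
    i <- i + k
  }
  paste(sentences, collapse = "\n")
}
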