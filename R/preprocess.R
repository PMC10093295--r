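#' Normalize raw report text into a token sequence
#'
#' Applies the audit's fixed normalization pipeline, in order: newlines to
#' spaces; tokenization on whitespace/punctuation boundaries (hyphens and
#' other intra-word punctuation split tokens); lowercasing; lemmatization;
#' removal of tokens containing digits; removal of single-character tokens;
#' removal of stopwords. The result is order-preserving and idempotent:
#' re-processing the joined output reproduces it.
#'
#' Unrecognized abbreviations and misspellings pass through unchanged (the
#' default lemmatizer is the identity); a language-specific lemmatizer can
#' be plugged in, and must be a total lowercase-to-lowercase function.
#'
#' @param text A single character string (may be empty).
#' @param stopwords Character vector of lowercase stopwords.
#' @param lemmatize A word -> word function, applied per token.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' preprocess_text("De MRI-scan 3 toont 2 laesies.", stopwords = "de")
preprocess_text <- function(text, stopwords = character(), lemmatize = identity) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  x <- gsub("[\r\n]+", " ", text)
  toks <- unlist(strsplit(x, "[^[:alnum:]]+"), use.names = FALSE)
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character())
  toks <- tolower(toks)
  toks <- vapply(toks, function(w) as.character(lemmatize(w)), character(1),
                 USE.NAMES = FALSE)
  toks <- toks[!grepl("[0-9]", toks)]
  toks <- toks[nchar(toks) >= 2]
  toks <- toks[!(toks %in% stopwords)]
  toks
}

#' Tokenize every report in a corpus
#'
#' @param corpus Tibble with `id`, `text`, `label`.
#' @inheritParams preprocess_text
#' @return Tibble with `id`, `tokens` (list column), `label`.
#' @export
tokenize_corpus <- function(corpus, stopwords = character(), lemmatize = identity) {
  stopifnot(all(c("id", "text", "label") %in% names(corpus)))
  tibble::tibble(
    id = corpus$id,
    tokens = lapply(corpus$text, preprocess_text,
                    stopwords = stopwords, lemmatize = lemmatize),
    label = as.integer(corpus$label)
  )
}

#' Apply an annotation-review outcome table to a corpus
#'
#' Mechanizes a relabeling protocol: reports reviewed as `"exclusion"` are
#' removed from the corpus (e.g. not eligible for the dataset at all), those
#' reviewed as `"relabel"` get `new_label`, and `"confirm"`, `"ambiguity"`
#' and `"exception"` outcomes leave the corpus unchanged. Record counts
#' before and after are attached so bookkeeping can be audited.
#'
#' @param corpus Tibble with at least `id` and `label`.
#' @param review Data frame with columns `id`, `outcome` (one of `confirm`,
#'   `relabel`, `ambiguity`, `exception`, `exclusion`) and optionally
#'   `new_label` for relabeled reports.
#' @return The filtered corpus, with attributes `n_before`, `n_excluded`,
#'   `n_relabeled`.
#' @export
apply_annotation_review <- function(corpus, review) {
  stopifnot(all(c("id", "outcome") %in% names(review)))
  ok <- c("confirm", "relabel", "ambiguity", "exception", "exclusion")
  if (!all(review$outcome %in% ok)) {
    stop("unknown review outcome(s): ",
         paste(setdiff(unique(review$outcome), ok), collapse = ", "),
         call. = FALSE)
  }
  if (!all(review$id %in% corpus$id)) {
    stop("review references unknown report id(s)", call. = FALSE)
  }
  n_before <- nrow(corpus)
  relab <- review[review$outcome == "relabel", , drop = FALSE]
  if (nrow(relab)) {
    if (is.null(relab$new_label) || anyNA(relab$new_label)) {
      stop("`new_label` required for relabeled reports", call. = FALSE)
    }
    corpus$label[match(relab$id, corpus$id)] <- as.integer(relab$new_label)
  }
  excl <- review$id[review$outcome == "exclusion"]
  out <- corpus[!(corpus$id %in% excl), , drop = FALSE]
  attr(out, "n_before") <- n_before
  attr(out, "n_excluded") <- length(excl)
  attr(out, "n_relabeled") <- nrow(relab)
  out
}
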