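#' Read and write report corpora as JSONL
#'
#' One JSON object per line. Raw corpora carry `id`, `text`, `label`;
#' tokenized corpora carry `id`, `tokens`, `label`.
#'
#' @param corpus Tibble with columns `id`, `label` and either `text` or
#'   `tokens` (list column).
#' @param path File path.
#' @return `read_corpus_jsonl` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- list(id = corpus$id[i], label = corpus$label[i])
    if ("text" %in% names(corpus)) rec$text <- corpus$text[i]
    if ("tokens" %in% names(corpus)) rec$tokens <- corpus$tokens[[i]]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- tibble::tibble(
    id = vapply(recs, `[[`, character(1), "id"),
    label = vapply(recs, function(r) as.integer(r$label), integer(1))
  )
  if (!is.null(recs[[1]]$text)) {
    out$text <- vapply(recs, `[[`, character(1), "text")
  }
  if (!is.null(recs[[1]]$tokens)) {
    out$tokens <- lapply(recs, function(r) as.character(r$tokens))
  }
  out[, intersect(c("id", "text", "tokens", "label"), names(out))]
}

#' Read and write lexicons as JSON
#'
#' Serializes the word-role lists (`valid`, `perhaps_valid`, `wrong`,
#' `filler` for synthetic lexicons) and the `normalization_map`.
#'
#' @param lexicon A `synthetic_lexicon` or `domain_lexicon`.
#' @param path File path.
#' @export
write_lexicon_json <- function(lexicon, path) {
  jsonlite::write_json(unclass(lexicon), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_lexicon_json
#' @export
read_lexicon_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  nmap <- as.list(unlist(x$normalization_map) %||% character())
  if (!is.null(x$filler)) {
    synthetic_lexicon(valid = lapply(x$valid, as.character),
                      perhaps_valid = lapply(x$perhaps_valid, as.character),
                      wrong = as.character(unlist(x$wrong) %||% character()),
                      filler = as.character(unlist(x$filler) %||% character()),
                      normalization_map = nmap)
  } else {
    domain_lexicon(valid = lapply(x$valid, as.character),
                   perhaps_valid = lapply(x$perhaps_valid, as.character),
                   wrong = as.character(unlist(x$wrong) %||% character()),
                   normalization_map = nmap)
  }
}

#' Packaged default stopword list
#'
#' Returns the bundled Dutch stopword list (one word per line, UTF-8), or
#' reads a user-supplied stopword file.
#'
#' @param path Optional path to a stopword file; defaults to the packaged
#'   Dutch list.
#' @return Character vector of lowercase stopwords.
#' @export
default_stopwords <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stopwords_nl.txt", package = "xaudit")
  if (!file.exists(path)) stop("stopword file not found: ", path, call. = FALSE)
  words <- readLines(path, encoding = "UTF-8")
  tolower(trimws(words[nzchar(trimws(words))]))
}
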