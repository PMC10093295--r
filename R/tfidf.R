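#' Fit a TF-IDF weighting model
#'
#' Standard smoothed-idf variant: `idf(w) = ln((1 + n_docs) / (1 + df(w))) + 1`
#' with raw term counts, followed by L2 normalization of each document
#' vector. Words unseen at fit time are ignored at transform time.
#'
#' @param corpus Tokenized corpus tibble (with a `tokens` list column) or a
#'   plain list of character vectors.
#' @return An object of class `tfidf_model` with fields `vocabulary`
#'   (word -> column index), `doc_freq`, `n_docs`, `idf`.
#' @export
fit_tfidf <- function(corpus) {
  docs <- if (is.data.frame(corpus)) corpus$tokens else corpus
  stopifnot(length(docs) > 0)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  df <- integer(length(vocab))
  names(df) <- vocab
  for (d in docs) {
    u <- unique(d)
    df[u] <- df[u] + 1L
  }
  n <- length(docs)
  structure(
    list(vocabulary = stats::setNames(seq_along(vocab), vocab),
         doc_freq = df, n_docs = n,
         idf = log((1 + n) / (1 + df)) + 1),
    class = "tfidf_model"
  )
}

#' Transform token sequences into TF-IDF vectors
#'
#' @param model A fitted [fit_tfidf()] model.
#' @param tokens A character vector (one document) or a list of character
#'   vectors.
#' @return A numeric vector (single document) or matrix (documents in rows),
#'   columns named by the model vocabulary, each row L2-normalized.
#' @export
tfidf_transform <- function(model, tokens) {
  if (!inherits(model, "tfidf_model")) {
    stop("`model` must be a fitted tfidf_model (call fit_tfidf() first)",
         call. = FALSE)
  }
  single <- !is.list(tokens)
  docs <- if (single) list(as.character(tokens)) else tokens
  vocab <- names(model$vocabulary)
  out <- matrix(0, nrow = length(docs), ncol = length(vocab),
                dimnames = list(NULL, vocab))
  for (i in seq_along(docs)) {
    idx <- match(docs[[i]], vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tf <- tabulate(idx, nbins = length(vocab))
      v <- tf * model$idf
      nrm <- sqrt(sum(v^2))
      if (nrm > 0) v <- v / nrm
      out[i, ] <- v
    }
  }
  if (single) out[1, ] else out
}
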