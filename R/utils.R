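`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a master seed together with a stage label so that every stage of a
#' pipeline run draws from its own reproducible stream. Adding a new stage
#' never perturbs the streams of existing stages.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# FNV-1a hash of a string, returned as 8 hex digits; used for run manifests.
fnv1a_hex <- function(x) {
  h <- 2166136261
  for (code in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
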