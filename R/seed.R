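#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the simulator and the classifier flows from one explicit
#' master seed. Sub-modules (per subject, per wrist, per annotator, per CV
#' fold, ...) draw their own seed by hashing the master seed together with a
#' string key, so any stage can be re-run in isolation and still reproduce
#' the exact stream it saw inside a full run.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components identifying the consumer.
#' @return An integer in [0, 2^31 - 1), suitable for \code{set.seed()}.
#' @export
split_seed <- function(seed, ...) {
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  # FNV-1a over the key bytes, folded into the positive 31-bit range.
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
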