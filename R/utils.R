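# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## One-line-per-event logging. INFO for stage progress, WARNING for dropped
## samples / skipped combinations; messages are machine-parsable:
## "<LEVEL> <context>: <text>".
cs_log <- function(level = c("INFO", "WARNING"), context, text) {
  level <- match.arg(level)
  msg <- sprintf("%s %s: %s", level, context, text)
  if (level == "WARNING") warning(msg, call. = FALSE) else message(msg)
  invisible(msg)
}

cs_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## FNV-1a 32-bit hash of a character scalar; used to derive per-label RNG
## streams and provenance hashes. Returned as integer in [0, 2^31).
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with the byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit multiply without losing double precision: split at 2^16
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  as.integer(h %% 2^31)
}

## Derive a child seed from a master seed and a string label.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + as.numeric(fnv1a32(label))) %% 2^31)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
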