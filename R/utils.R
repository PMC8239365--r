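# internal helpers: structured errors, deterministic hashing, seed streams

uk_error <- function(msg, class = "upstreamkit_error", call. = FALSE) {
  stop(structure(
    class = c(class, "upstreamkit_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

uk_format_error <- function(msg) uk_error(msg, class = "upstreamkit_format_error")

uk_precondition_error <- function(msg) uk_error(msg, class = "upstreamkit_precondition_error")

uk_warn <- function(msg, class = "upstreamkit_warning") {
  warning(warningCondition(msg, class = c(class, "upstreamkit_warning")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits.
# Used to stamp a content hash of the pipeline configuration into every
# output file (provenance) without pulling in a digest dependency.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- (h - lo) + bitwXor(as.integer(lo), b)
    # h * 16777619 mod 2^32, split to stay inside double precision
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  hex <- "0123456789abcdef"
  out <- character(8)
  for (i in 8:1) {
    out[i] <- substr(hex, h %% 16 + 1, h %% 16 + 1)
    h <- h %/% 16
  }
  paste(out, collapse = "")
}

# Deterministic sub-seed derivation: independent streams per artifact so
# changing one stage's seed leaves the others bit-identical.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 1000003 + 7919 * k) %% 2147483647)
}

# Stable number formatting for deterministic text output.
fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}
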