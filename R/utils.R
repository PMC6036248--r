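#' @keywords internal
"_PACKAGE"

## Deterministic seed derivation: one master seed, documented per-context
## derivation so any single protocol cell is reproducible in isolation.
## Linear-congruential mixing kept below 2^31 (R integers are 32-bit).

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master integer seed with an arbitrary sequence of tags (integers
#' or strings, e.g. protocol name, repetition, combination index) into a
#' child seed. The same master seed and tags always give the same child, and
#' different tag paths give effectively independent streams.
#'
#' @param seed master integer seed.
#' @param ... tags (character or integerish scalars) identifying the context.
#' @return an integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  tags <- list(...)
  x <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (tag in tags) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag))
    x <- (x * 69069 + as.double(tag) * 104729 + 1) %% 2147483647
  }
  as.integer(x)
}

## Split an integer quota q as evenly as possible over k cells; the first
## (q mod k) cells receive the extra row. Deterministic in cell order.
split_quota <- function(q, k) {
  base <- q %/% k
  base + as.integer(seq_len(k) <= q %% k)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
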