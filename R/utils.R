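# Deterministic seed derivation and scoped RNG use.

#' Derive a stage-specific sub-seed from a master seed
#'
#' Hashes a label into the master seed so that pipeline stages and per-bin
#' null models draw from independent, individually reproducible RNG
#' streams. The result is always a nonnegative 32-bit integer.
#'
#' @param master integer master seed.
#' @param label character stage/context label.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master))
  chars <- utf8ToInt(as.character(label))
  h <- 0
  for (ch in chars) h <- (h * 131 + ch) %% 2147483563
  as.integer((abs(as.numeric(master)) * 48271 + h + 1) %% 2147483563)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
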