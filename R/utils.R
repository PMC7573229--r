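# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a single pipeline seed so stages can be
# rerun independently with stable streams. Kept below .Machine$integer.max.
derive_seed <- function(seed, stage_offset) {
  (as.integer(seed) * 7919L + as.integer(stage_offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ktscreen <- function(...) stop(..., call. = FALSE)
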