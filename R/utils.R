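## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("hm_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("hm_degenerate_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    stop_validation(what, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(x)
}

assert_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(what, " must be TRUE or FALSE")
  }
  invisible(x)
}

## Derive a reproducible child seed from a base seed and a stream index,
## staying below .Machine$integer.max.
child_seed <- function(seed, stream) {
  ## double arithmetic: products stay far below 2^53, result below 2^31
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %%
               2147483562)
}
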