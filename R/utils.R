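assert_probability <- function(x, arg) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    shown <- if (is.numeric(x) && length(x) == 1L) format(x) else class(x)[1]
    abort(sprintf("`%s` must be a single probability in [0, 1] (got %s).",
                  arg, shown),
          class = "strainseg_validation_error")
  }
  invisible(x)
}

assert_count <- function(x, arg, allow_zero = FALSE, min = if (allow_zero) 0L else 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x == as.integer(x) && x >= min
  if (!ok) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min),
          class = "strainseg_validation_error")
  }
  invisible(as.integer(x))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the current stream is used as-is.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
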