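# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` uses the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministically derive a child seed from a root seed and an index, so
# grid cells and replicates are independent yet reproducible. Stays below
# 2^31 - 1 (R integer range).
derive_seed <- function(root, index) {
  stopifnot(is.numeric(root), is.numeric(index), index >= 0)
  (((root %% 1000003) * 1009 + index * 7919) %% 2147483629) + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}
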