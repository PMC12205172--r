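# Internal helpers: seed management and small validators.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic sub-seed derivation from one user-facing seed. Kept well
# inside 32-bit integer range.
derive_seed <- function(seed, counter) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2099 + counter) %% 2147483647L
}

stop_if_not_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("`%s` contains non-finite values (first at row %d, column %d)",
                 name, bad[1L], bad[2L]), call. = FALSE)
  }
  invisible(x)
}

check_square <- function(x, name = deparse(substitute(x))) {
  stop_if_not_matrix(x, name)
  if (nrow(x) != ncol(x))
    stop(sprintf("`%s` must be square (got %d x %d)", name, nrow(x), ncol(x)),
         call. = FALSE)
  invisible(x)
}

# upper-triangle indices as a 2-column matrix, i < j
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}
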