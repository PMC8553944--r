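# Internal helpers shared across modules.

# Derive a reproducible sub-seed from one global seed and a stage label, so
# that every stochastic stage draws from its own labelled stream.  Kept below
# .Machine$integer.max.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = leave the
# global stream alone).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Permutation / bootstrap p-values never go below 1/(n+1).
perm_pval <- function(n_extreme, n_perm) {
  (n_extreme + 1) / (n_perm + 1)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
}
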