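# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so seeded generators behave as pure functions.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Column variances without forming a centered copy per column.
col_vars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m * m) - n * mu^2) / (n - 1)
}

one_hot <- function(f, levels) {
  m <- matrix(0, length(f), length(levels),
              dimnames = list(names(f), levels))
  m[cbind(seq_along(f), match(f, levels))] <- 1
  m
}
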