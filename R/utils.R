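# Internal helpers shared across the package.

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so package functions never disturb
# the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage offset, kept inside
# 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

msgf <- function(verbose, fmt, ...) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
}

# Pearson correlation of each column of A against a single vector y.
# A: n x m, y: length n.  Returns length-m vector.  Faster than looping
# cor() and used in hot paths (resembled-fake candidate ranking).
cor_with <- function(A, y) {
  n <- nrow(A)
  y <- y - mean(y)
  sy <- sqrt(sum(y^2))
  Ac <- A - matrix(colMeans(A), n, ncol(A), byrow = TRUE)
  sA <- sqrt(colSums(Ac^2))
  out <- as.vector(crossprod(Ac, y)) / (sA * sy)
  out[!is.finite(out)] <- 0
  out
}
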