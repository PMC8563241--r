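# Internal numerical helpers shared across modules.

# Cholesky with escalating diagonal jitter. Relationship matrices are PSD in
# exact arithmetic but can be numerically semidefinite (e.g. clones of a
# founder); the jitter ladder starts at 1e-10 * mean(diag) and grows tenfold.
chol_jitter <- function(M, max_tries = 8L) {
  scale <- mean(diag(M))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (k in 0:max_tries) {
    jit <- if (k == 0L) 0 else 1e-10 * scale * 10^(k - 1L)
    L <- tryCatch(chol(M + diag(jit, nrow(M))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("matrix is not positive definite within jitter tolerance")
}

# Solve M x = b given U = chol(M) (upper triangular).
chol_solve <- function(U, b) {
  backsolve(U, backsolve(U, b, transpose = TRUE))
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Factor with levels in order of first appearance (reference-level coding
# convention used throughout: the first level seen is the reference).
factor_first_appearance <- function(x) {
  x <- as.character(x)
  factor(x, levels = unique(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
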