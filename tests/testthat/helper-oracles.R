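# Independent restricted-likelihood oracle, via error contrasts K'y with
# K an orthonormal basis of the null space of X'. Shares no code with
# reml_estimate (which works through the projection matrix P).
kcontrast_loglik <- function(theta, y, X, Ga, Gd = NULL) {
  n <- length(y)
  p <- ncol(X)
  K <- qr.Q(qr(X), complete = TRUE)[, (p + 1):n, drop = FALSE]
  V <- theta[1] * Ga + diag(theta[length(theta)], n)
  if (!is.null(Gd)) V <- V + theta[2] * Gd
  M <- crossprod(K, V %*% K)
  L <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  z <- crossprod(K, y)
  as.numeric(-0.5 * (2 * sum(log(diag(L))) +
                       sum(backsolve(L, z, transpose = TRUE)^2) +
                       (n - p) * log(2 * pi)))
}

# design pieces (y, X, record-level relationship submatrices) for the oracle
oracle_pieces <- function(dm, A, D = NULL) {
  idx <- dm$record_animal
  list(y = dm$y, X = dm$X,
       Ga = unclass(A)[idx, idx, drop = FALSE],
       Gd = if (!is.null(D)) unclass(D)[idx, idx, drop = FALSE])
}
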