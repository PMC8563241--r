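#' Solve Henderson's mixed-model equations
#'
#' Given variance components, solves the normal equations whose coefficient
#' blocks are `X'X`, `X'Z`, `X'W`, `Z'Z + A^-1 k_a`, `Z'W`, and
#' `W'W + D^-1 k_d` for `(beta_hat, a_hat, d_hat)` against the right-hand
#' side `(X'y, Z'y, W'y)`,
#' with variance ratios `k_a = sigma2_e / sigma2_a` and
#' `k_d = sigma2_e / sigma2_d`. A component estimated at the zero boundary
#' drops its block from the equations and the corresponding BLUP vector is
#' returned as exact zeros. Relationship-matrix inverses use dense Cholesky
#' with escalating jitter. Animals without records receive BLUPs through the
#' relationship structure.
#'
#' @param dm design matrices from [build_design_matrices()].
#' @param A,D relationship matrices over the pedigree animals.
#' @param vc a `kr_varcomp` (or a named list with `sigma2_a`, `sigma2_d`,
#'   `sigma2_e`); `sigma2_e` must be positive.
#' @return an object of class `kr_mme`: `beta_hat` (named), `a_hat`, `d_hat`
#'   (named per-animal BLUPs, grams), and `solution_residual_norm` (maximum
#'   absolute normal-equation residual relative to the right-hand side).
#' @export
solve_mme <- function(dm, A, D, vc) {
  stopifnot(inherits(dm, "kr_design"))
  if (!is.numeric(vc$sigma2_e) || vc$sigma2_e <= 0)
    stop("solve_mme requires sigma2_e > 0")
  n <- dm$n
  p <- ncol(dm$X)
  q <- dm$n_animals
  ids <- dm$animal_ids
  X <- dm$X
  y <- dm$y
  idx <- dm$record_animal
  use_a <- vc$sigma2_a > 0
  use_d <- vc$sigma2_d > 0

  # Z'Z is diagonal (one record -> one animal); X'Z and Z'y by aggregation
  cnt <- tabulate(idx, nbins = q)
  XtZ <- matrix(0, p, q)
  agg <- rowsum(X, group = idx, reorder = FALSE)
  XtZ[, as.integer(rownames(agg))] <- t(agg)
  Zty <- numeric(q)
  aggy <- rowsum(y, group = idx, reorder = FALSE)
  Zty[as.integer(rownames(aggy))] <- aggy

  blocks <- list(list(name = "beta", size = p))
  if (use_a) blocks <- c(blocks, list(list(name = "a", size = q)))
  if (use_d) blocks <- c(blocks, list(list(name = "d", size = q)))
  dim_tot <- sum(vapply(blocks, `[[`, 0, "size"))
  C <- matrix(0, dim_tot, dim_tot)
  rhs <- numeric(dim_tot)

  off <- stats::setNames(
    cumsum(c(0, utils::head(vapply(blocks, `[[`, 0, "size"), -1L))),
    vapply(blocks, `[[`, "", "name"))
  bi <- function(nm, size) off[[nm]] + seq_len(size)

  ib <- bi("beta", p)
  C[ib, ib] <- crossprod(X)
  rhs[ib] <- crossprod(X, y)
  ZtZ <- diag(cnt, q)
  if (use_a) {
    ia <- bi("a", q)
    Ainv <- chol2inv(chol_jitter(unclass(A)))
    C[ia, ia] <- ZtZ + (vc$sigma2_e / vc$sigma2_a) * Ainv
    C[ib, ia] <- XtZ
    C[ia, ib] <- t(XtZ)
    rhs[ia] <- Zty
  }
  if (use_d) {
    id_ <- bi("d", q)
    Dinv <- chol2inv(chol_jitter(unclass(D)))
    C[id_, id_] <- ZtZ + (vc$sigma2_e / vc$sigma2_d) * Dinv
    C[ib, id_] <- XtZ
    C[id_, ib] <- t(XtZ)
    rhs[id_] <- Zty
    if (use_a) {
      ia <- bi("a", q)
      C[ia, id_] <- ZtZ
      C[id_, ia] <- ZtZ
    }
  }

  sol <- tryCatch(solve(C, rhs),
                  error = function(e) stop("singular mixed-model equations: ",
                                           conditionMessage(e)))
  resid_norm <- max(abs(C %*% sol - rhs)) / max(abs(rhs), 1)

  beta_hat <- stats::setNames(sol[ib], colnames(X))
  a_hat <- stats::setNames(rep(0, q), ids)
  d_hat <- stats::setNames(rep(0, q), ids)
  if (use_a) a_hat[] <- sol[bi("a", q)]
  if (use_d) d_hat[] <- sol[bi("d", q)]

  structure(list(beta_hat = beta_hat, a_hat = a_hat, d_hat = d_hat,
                 solution_residual_norm = resid_norm),
            class = "kr_mme")
}

#' @export
print.kr_mme <- function(x, ...) {
  cat("Mixed-model equation solution\n")
  cat("  fixed effects:\n")
  print(round(x$beta_hat, 4))
  cat(sprintf("  %d additive BLUPs (sd %.4g), %d dominance BLUPs (sd %.4g)\n",
              length(x$a_hat), stats::sd(x$a_hat),
              length(x$d_hat), stats::sd(x$d_hat)))
  cat(sprintf("  relative normal-equation residual: %.3g\n",
              x$solution_residual_norm))
  invisible(x)
}
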