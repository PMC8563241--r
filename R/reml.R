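#' REML estimation of additive, dominance and residual variances
#'
#' Fits the animal model `y = Xb + Za + Wd + e` with
#' `var(a) = A sigma2_a`, `var(d) = D sigma2_d`, `var(e) = I sigma2_e`
#' by restricted maximum likelihood. The iteration is EM-REML, which
#' guarantees a non-decreasing restricted log-likelihood, accelerated by an
#' average-information (quasi-Newton) step whenever that step does not
#' decrease the likelihood. Components are constrained non-negative; an
#' additive or dominance component that stays pinned at the zero boundary for
#' three consecutive iterations is fixed at exactly 0 and removed from the
#' working model. The residual variance is kept above a small positive floor
#' so the marginal covariance stays invertible.
#'
#' The computation works on the marginal covariance of the records,
#' `V = sigma2_a Z A Z' + sigma2_d W D W' + sigma2_e I` (an n x n matrix,
#' n = number of records), with the EM updates expressed through the REML
#' projection matrix `P = V^-1 - V^-1 X (X'V^-1 X)^-1 X'V^-1`:
#' for a component with structure `G_i` and `q_i` levels,
#' `theta_i <- theta_i + theta_i^2 / q_i * (y'P G_i P y - tr(P G_i))`.
#' Standard errors come from the inverse average-information matrix at
#' convergence; the SE of h2 uses the delta method.
#'
#' @param dm design matrices from [build_design_matrices()].
#' @param A additive relationship matrix of the pedigree.
#' @param D dominance relationship matrix (may be `NULL` when `random`
#'   excludes `"dominance"`).
#' @param init optional named numeric `c(a=, d=, e=)` of starting values;
#'   default splits the phenotypic variance equally.
#' @param tol convergence tolerance on the relative change of each component
#'   (the log-likelihood must also change by less than 1e-6).
#' @param max_iter maximum number of iterations; if reached, the fit is
#'   returned with `converged = FALSE` and a warning.
#' @param random which genetic components to fit.
#' @param verbose print per-iteration components and log-likelihood.
#' @return an object of class `kr_varcomp`: variance components, their sum
#'   `sigma2_p`, `h2`, `d_ratio`, component standard errors, `se_h2`,
#'   the restricted log-likelihood and its per-iteration trace, `converged`,
#'   and `n_iter`.
#' @export
reml_estimate <- function(dm, A, D = NULL, init = NULL, tol = 1e-8,
                          max_iter = 100L,
                          random = c("additive", "dominance"),
                          verbose = FALSE) {
  stopifnot(inherits(dm, "kr_design"))
  random <- match.arg(random, several.ok = TRUE)
  use_a <- "additive" %in% random
  use_d <- "dominance" %in% random
  if (use_d && is.null(D)) stop("dominance requested but D is NULL")
  n <- dm$n
  p <- ncol(dm$X)
  if (n <= p) stop("fewer records than fixed-effect parameters")
  idx <- dm$record_animal
  y <- dm$y
  X <- dm$X
  q_lev <- dm$n_animals
  Ga <- if (use_a) unclass(A)[idx, idx, drop = FALSE] else NULL
  Gd <- if (use_d) unclass(D)[idx, idx, drop = FALSE] else NULL

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  n_active <- 1L + use_a + use_d
  th <- c(a = if (use_a) vy / n_active else 0,
          d = if (use_d) vy / n_active else 0,
          e = vy / n_active)
  if (!is.null(init)) {
    init <- init[intersect(names(init), names(th))]
    if (any(init < 0)) stop("initial variance components must be >= 0")
    th[names(init)] <- init
  }
  fixed0 <- c(a = !use_a, d = !use_d)
  th[c("a", "d")][fixed0] <- 0
  floor_e <- 1e-8 * vy
  pin_eps <- 1e-6 * vy
  th["e"] <- max(th["e"], floor_e)
  fixed_e <- FALSE  # residual pinned at its positive floor (boundary fit)
  pin_count <- c(a = 0L, d = 0L, e = 0L)
  lower <- c(a = 0, d = 0, e = floor_e)

  build_V <- function(th) {
    V <- diag(th[["e"]], n)
    if (th[["a"]] > 0) V <- V + th[["a"]] * Ga
    if (th[["d"]] > 0) V <- V + th[["d"]] * Gd
    V
  }
  # log-likelihood only (no n x n inverse): used to vet AI proposals
  eval_ll <- function(th) {
    L <- chol_jitter(build_V(th))
    ViXy <- chol_solve(L, cbind(X, y))
    ViX <- ViXy[, seq_len(p), drop = FALSE]
    Viy <- ViXy[, p + 1L]
    cM <- chol(crossprod(X, ViX))
    Py <- Viy - ViX %*% chol_solve(cM, crossprod(X, Viy))
    ll <- -0.5 * (2 * sum(log(diag(L))) + 2 * sum(log(diag(cM))) +
                    sum(y * Py) + (n - p) * log(2 * pi))
    list(ll = as.numeric(ll), L = L, ViX = ViX, cM = cM, Py = as.numeric(Py))
  }
  # full state: adds the projection matrix P for traces and the AI matrix
  full_eval <- function(th) {
    st <- eval_ll(th)
    Vi <- chol2inv(st$L)
    P <- Vi - st$ViX %*% chol_solve(st$cM, t(st$ViX))
    st$P <- P
    st
  }
  comp_stats <- function(st) {
    w <- st$Py
    act <- c("a", "d", "e")[c(!fixed0[["a"]], !fixed0[["d"]], !fixed_e)]
    Tm <- matrix(0, n, length(act), dimnames = list(NULL, act))
    trPG <- wGw <- stats::setNames(numeric(length(act)), act)
    for (cmp in act) {
      G <- switch(cmp, a = Ga, d = Gd, e = NULL)
      t_i <- if (is.null(G)) w else G %*% w
      Tm[, cmp] <- t_i
      trPG[cmp] <- if (is.null(G)) sum(diag(st$P)) else sum(st$P * G)
      wGw[cmp] <- sum(w * t_i)
    }
    AI <- 0.5 * crossprod(Tm, st$P %*% Tm)
    grad <- -0.5 * (trPG - wGw)
    list(act = act, trPG = trPG, wGw = wGw, AI = AI, grad = grad)
  }
  q_of <- function(cmp) if (cmp == "e") n else q_lev

  st <- full_eval(th)
  trace <- st$ll
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    cs <- comp_stats(st)
    th_prop <- NULL
    if (it >= 3L) {
      delta_full <- tryCatch(
        stats::setNames(as.numeric(solve(cs$AI, cs$grad)), cs$act),
        error = function(e) NULL)
      if (!is.null(delta_full)) {
        # a component driven through its bound by the Newton step signals
        # the boundary: try an active-set move (component held at the bound,
        # the Newton step re-solved for the rest) before the damped step
        at_bound <- names(delta_full)[th[names(delta_full)] + delta_full <
                                        lower[names(delta_full)]]
        try_sets <- if (length(at_bound)) list(at_bound, character(0))
                    else list(character(0))
        for (zs in try_sets) {
          act2 <- setdiff(cs$act, zs)
          if (!length(act2)) next
          delta <- tryCatch(
            stats::setNames(as.numeric(
              solve(cs$AI[act2, act2, drop = FALSE], cs$grad[act2])), act2),
            error = function(e) NULL)
          if (is.null(delta)) next
          step <- 1
          for (k in 1:8) {
            cand <- th
            cand[zs] <- lower[zs]
            cand[act2] <- th[act2] + step * delta
            feasible <- all(cand[act2] > lower[act2])
            if (feasible) {
              ll_c <- eval_ll(cand)$ll
              if (is.finite(ll_c) && ll_c >= st$ll) {
                th_prop <- cand
                break
              }
            }
            step <- step / 2
          }
          if (!is.null(th_prop)) break
        }
      }
    }
    if (is.null(th_prop)) {  # monotone EM fallback
      th_prop <- th
      for (cmp in cs$act) {
        upd <- th[[cmp]] + th[[cmp]]^2 / q_of(cmp) *
          (cs$wGw[[cmp]] - cs$trPG[[cmp]])
        th_prop[cmp] <- max(upd, 0)
      }
      th_prop["e"] <- max(th_prop[["e"]], floor_e)
    }
    for (cmp in c("a", "d")) {
      if (fixed0[[cmp]]) next
      if (th_prop[[cmp]] == 0 || th_prop[[cmp]] < pin_eps) {
        pin_count[cmp] <- pin_count[[cmp]] + 1L
        if (pin_count[[cmp]] >= 3L) {
          fixed0[cmp] <- TRUE
          th_prop[cmp] <- 0
        }
      } else pin_count[cmp] <- 0L
    }
    if (!fixed_e) {
      if (th_prop[["e"]] <= floor_e) {
        pin_count["e"] <- pin_count[["e"]] + 1L
        if (pin_count[["e"]] >= 3L) fixed_e <- TRUE
      } else pin_count["e"] <- 0L
    }
    st_new <- full_eval(th_prop)
    rel <- max(abs(th_prop - th) / pmax(abs(th), 1e-10 * vy))
    dll <- st_new$ll - st$ll
    if (dll < 0) {
      # both step types are ascent directions in exact arithmetic, so a
      # decrease means working precision is exhausted: stop without moving
      converged <- rel < 1e-4
      break
    }
    trace <- c(trace, st_new$ll)
    th <- th_prop
    st <- st_new
    if (verbose)
      message(sprintf("iter %3d: a=%.6g d=%.6g e=%.6g logL=%.6f",
                      it, th[["a"]], th[["d"]], th[["e"]], st$ll))
    if (rel < tol && abs(dll) < 1e-6) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")

  # standard errors from the inverse AI matrix at the final estimates
  cs <- comp_stats(st)
  cov3 <- matrix(0, 3, 3, dimnames = list(c("a", "d", "e"), c("a", "d", "e")))
  cov_act <- tryCatch(solve(cs$AI), error = function(e) NULL)
  if (!is.null(cov_act)) cov3[cs$act, cs$act] <- cov_act
  se <- sqrt(pmax(diag(cov3), 0))
  sp <- th[["a"]] + th[["d"]] + th[["e"]]
  h2 <- if (sp > 0) th[["a"]] / sp else NA_real_
  d_ratio <- if (sp > 0) th[["d"]] / sp else NA_real_
  se_h2 <- NA_real_
  if (!is.null(cov_act) && sp > 0) {
    g <- c(a = (th[["d"]] + th[["e"]]) / sp^2,
           d = -th[["a"]] / sp^2,
           e = -th[["a"]] / sp^2)
    se_h2 <- sqrt(max(as.numeric(t(g) %*% cov3 %*% g), 0))
  }

  structure(list(
    sigma2_a = unname(th[["a"]]), sigma2_d = unname(th[["d"]]),
    sigma2_e = unname(th[["e"]]), sigma2_p = unname(sp),
    h2 = h2, d_ratio = d_ratio,
    se_components = stats::setNames(se, c("a", "d", "e")),
    se_h2 = se_h2,
    loglik = st$ll, loglik_trace = trace,
    converged = converged, n_iter = n_iter,
    fixed_zero = fixed0, n = n, random = random
  ), class = "kr_varcomp")
}

#' @export
print.kr_varcomp <- function(x, ...) {
  cat("Variance components (REML)\n")
  cat(sprintf("  sigma2_a = %.4f (SE %.4f)\n", x$sigma2_a,
              x$se_components[["a"]]))
  cat(sprintf("  sigma2_d = %.4f (SE %.4f)\n", x$sigma2_d,
              x$se_components[["d"]]))
  cat(sprintf("  sigma2_e = %.4f (SE %.4f)\n", x$sigma2_e,
              x$se_components[["e"]]))
  cat(sprintf("  sigma2_p = %.4f   h2 = %.3f (SE %.3f)   d/p = %.3f\n",
              x$sigma2_p, x$h2, x$se_h2, x$d_ratio))
  cat(sprintf("  logL = %.4f, %s in %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Derived genetic parameters
#'
#' Computes the total phenotypic variance and the two variance ratios from
#' additive, dominance and residual components:
#' `sigma2_p = sigma2_a + sigma2_d + sigma2_e`, `h2 = sigma2_a / sigma2_p`,
#' `d_ratio = sigma2_d / sigma2_p`. Vectorized over ages. No rounding is
#' applied here; see [format_genetic_parameters()] for the 2-decimal report
#' layer. A zero total variance yields `NA` ratios.
#'
#' @param sigma2_a,sigma2_d,sigma2_e variance components (grams^2), or a
#'   `kr_varcomp` object as the first argument.
#' @return a data frame with columns `sigma2_a`, `sigma2_d`, `sigma2_e`,
#'   `sigma2_p`, `h2`, `d_ratio`.
#' @export
genetic_parameters <- function(sigma2_a, sigma2_d = NULL, sigma2_e = NULL) {
  if (inherits(sigma2_a, "kr_varcomp")) {
    vc <- sigma2_a
    sigma2_a <- vc$sigma2_a
    sigma2_d <- vc$sigma2_d
    sigma2_e <- vc$sigma2_e
  }
  if (any(c(sigma2_a, sigma2_d, sigma2_e) < 0, na.rm = TRUE))
    stop("variance components must be >= 0")
  sp <- sigma2_a + sigma2_d + sigma2_e
  h2 <- ifelse(sp > 0, sigma2_a / sp, NA_real_)
  dr <- ifelse(sp > 0, sigma2_d / sp, NA_real_)
  data.frame(sigma2_a = sigma2_a, sigma2_d = sigma2_d, sigma2_e = sigma2_e,
             sigma2_p = sp, h2 = h2, d_ratio = dr)
}

#' Round genetic parameters for reporting
#'
#' @param gp data frame from [genetic_parameters()].
#' @param digits decimals for the ratios (variances keep 2 decimals).
#' @return the rounded data frame.
#' @export
format_genetic_parameters <- function(gp, digits = 2) {
  gp$sigma2_a <- round(gp$sigma2_a, 2)
  gp$sigma2_d <- round(gp$sigma2_d, 2)
  gp$sigma2_e <- round(gp$sigma2_e, 2)
  gp$sigma2_p <- round(gp$sigma2_p, 2)
  gp$h2 <- round(gp$h2, digits)
  gp$d_ratio <- round(gp$d_ratio, digits)
  gp
}
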