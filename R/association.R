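#' Tukey-Kramer multiple comparison of group means
#'
#' Studentized-range comparison of k group means with the Tukey-Kramer
#' adjustment for unequal group sizes:
#' `q_ij = |m_i - m_j| / sqrt(mse/2 * (1/n_i + 1/n_j))`, referred to the
#' studentized-range distribution with k groups and the residual degrees of
#' freedom. Groups are summarized as a compact letter display built by the
#' insert-and-absorb sweep over groups sorted by decreasing mean, so the
#' letters are invariant to how the groups are labelled; groups sharing no
#' letter differ at level `alpha`.
#'
#' @param group_means named numeric vector of (least-square) means.
#' @param group_ns group sizes, same order.
#' @param mse residual mean square from the underlying model (> 0).
#' @param df_resid residual degrees of freedom (>= 1).
#' @param alpha significance level; differences with `p <= alpha` separate.
#' @return a list of class `kr_tukey` with the pairwise `p` matrix, the
#'   logical `significant` matrix, the `letters` display and `alpha`.
#' @export
tukey_kramer <- function(group_means, group_ns, mse, df_resid, alpha = 0.05) {
  k <- length(group_means)
  if (k < 2) stop("need at least two groups")
  if (length(group_ns) != k) stop("group_ns must match group_means")
  if (!is.finite(mse) || mse <= 0) stop("mse must be positive")
  if (!is.finite(df_resid) || df_resid < 1) stop("df_resid must be >= 1")
  nm <- names(group_means) %||% paste0("g", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(mse / 2 * (1 / group_ns[i] + 1 / group_ns[j]))
      qstat <- abs(group_means[i] - group_means[j]) / se
      p[i, j] <- p[j, i] <- stats::ptukey(qstat, k, df_resid,
                                          lower.tail = FALSE)
    }
  }
  diag(p) <- 1
  sig <- p <= alpha
  diag(sig) <- FALSE
  letters <- compact_letters(group_means, sig)
  structure(list(p = p, significant = sig, letters = letters, alpha = alpha),
            class = "kr_tukey")
}

# Compact letter display (insert-and-absorb). `sig` is a symmetric logical
# matrix of pairwise significance; groups sorted by decreasing mean so the
# largest mean carries "a".
compact_letters <- function(means, sig) {
  k <- length(means)
  nm <- rownames(sig)
  ord <- order(means, decreasing = TRUE)
  cols <- list(rep(TRUE, k))  # letter columns as membership over 1..k
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      gi <- ord[i]; gj <- ord[j]
      if (!sig[gi, gj]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[gi] && col[gj]) {  # split the offending column
          c1 <- col; c1[gj] <- FALSE
          c2 <- col; c2[gi] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb columns that are subsets of another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) for (b in seq_along(cols)) {
        if (a != b && !drop[a] && !drop[b] &&
            all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
          drop[a] <- TRUE
        else if (a < b && !drop[a] && !drop[b] &&
                 identical(cols[[a]], cols[[b]]))
          drop[b] <- TRUE
      }
      cols <- cols[!drop]
    }
  }
  # letter order follows the first (largest-mean) member of each column
  first_member <- vapply(cols, function(col) min(match(which(col), ord)),
                         numeric(1))
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(g) {
    paste0(letters[which(vapply(cols, `[`, TRUE, g))], collapse = "")
  }, character(1))
  stats::setNames(out, nm)
}

#' Genotype effect on a per-animal quantity
#'
#' Fits the linear model `value ~ genotype + sex` (sex optional), tests the
#' genotype effect with an F-test (type-II sum of squares: genotype adjusted
#' for sex), computes per-genotype least-square means averaged equally over
#' the observed sex levels, and compares genotype means with the
#' Tukey-Kramer procedure rendered as a compact letter display. Suitable for
#' body weight, dominance BLUPs, or normalized expression values.
#'
#' @param values numeric per-animal quantity.
#' @param genotype genotype factor (empty groups are dropped with a warning).
#' @param sex optional sex factor fitted as a fixed effect.
#' @param alpha significance level for the letter display.
#' @return an object of class `kr_genotype_comparison`: a `table` data frame
#'   (genotype, lsm, se, n, letter), `overall_p` (genotype F-test),
#'   `pairwise` p matrix, `mse`, `df_resid`, `alpha`.
#' @export
genotype_effect <- function(values, genotype, sex = NULL, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(genotype)
  if (!is.null(sex)) ok <- ok & !is.na(sex)
  values <- values[ok]
  g_raw <- genotype[ok]
  if (is.factor(g_raw) && any(table(g_raw) == 0)) {
    warning("empty genotype group(s) dropped: ",
            paste(names(which(table(g_raw) == 0)), collapse = ", "))
  }
  genotype <- factor_first_appearance(g_raw)
  if (nlevels(genotype) < 2) stop("need at least two non-empty genotype groups")
  d <- data.frame(value = values, genotype = genotype)
  if (!is.null(sex)) d$sex <- droplevels(factor_first_appearance(sex[ok]))
  use_sex <- !is.null(sex) && nlevels(d$sex) >= 2
  ns <- as.integer(table(d$genotype))
  names(ns) <- levels(d$genotype)

  if (stats::var(d$value) == 0) {
    # degenerate: identical values; no test to run
    tab <- data.frame(genotype = levels(d$genotype),
                      lsm = d$value[1], se = 0, n = ns,
                      letter = "a", stringsAsFactors = FALSE)
    return(structure(list(table = tab, overall_p = 1, pairwise = NULL,
                          mse = 0, df_resid = stats::lm(value ~ genotype,
                                                        d)$df.residual,
                          alpha = alpha),
                     class = "kr_genotype_comparison"))
  }

  form <- if (use_sex) value ~ genotype + sex else value ~ genotype
  fit <- stats::lm(form, data = d)
  if (fit$df.residual < 1) stop("no residual degrees of freedom")
  red <- if (use_sex) stats::lm(value ~ sex, data = d)
         else stats::lm(value ~ 1, data = d)
  overall_p <- stats::anova(red, fit)[2, "Pr(>F)"]
  mse <- stats::sigma(fit)^2

  # genotype LSMs: equal-weight average over observed sex levels
  glev <- levels(d$genotype)
  grid <- if (use_sex) expand.grid(genotype = glev, sex = levels(d$sex))
          else data.frame(genotype = glev)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                            data = grid, xlev = fit$xlevels)
  V <- stats::vcov(fit)
  lsm <- se <- stats::setNames(numeric(length(glev)), glev)
  for (g in glev) {
    cbar <- colMeans(mm[grid$genotype == g, , drop = FALSE])
    lsm[g] <- as.numeric(cbar %*% stats::coef(fit))
    se[g] <- sqrt(max(as.numeric(t(cbar) %*% V %*% cbar), 0))
  }

  tk <- tukey_kramer(lsm, ns, mse, fit$df.residual, alpha)
  tab <- data.frame(genotype = glev, lsm = unname(lsm), se = unname(se),
                    n = unname(ns), letter = unname(tk$letters[glev]),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, overall_p = overall_p, pairwise = tk$p,
                 mse = mse, df_resid = fit$df.residual, alpha = alpha),
            class = "kr_genotype_comparison")
}

#' @export
print.kr_genotype_comparison <- function(x, ...) {
  cat(sprintf("Genotype comparison (Tukey-Kramer, alpha = %.2f)\n", x$alpha))
  print(transform(x$table, lsm = round(lsm, 3), se = round(se, 3)),
        row.names = FALSE)
  cat(sprintf("  overall F-test p = %.4g\n", x$overall_p))
  invisible(x)
}

#' Pearson correlation between two per-animal quantities
#'
#' Standard product-moment correlation with a two-sided t-based p-value,
#' computed on complete pairs.
#'
#' @param x,y paired numeric vectors.
#' @return a list of class `kr_correlation` with `r`, `p` and `n` (pairs
#'   used). Zero variance in either variable yields `r = NA` with a warning.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; correlation undefined")
    return(structure(list(r = NA_real_, p = NA_real_, n = n),
                     class = "kr_correlation"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n),
            class = "kr_correlation")
}

#' @export
print.kr_correlation <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f (p = %.4g, n = %d)\n",
              x$r, x$p, x$n))
  invisible(x)
}
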