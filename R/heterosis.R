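#' Least-square mean of a line
#'
#' Fits a fixed-effects linear model within one line (group) and returns the
#' marginal mean averaged with equal weight over all observed combinations of
#' the fixed-factor levels (classical LSMEANS convention). Factors observed
#' at a single level within the group are absorbed into the intercept.
#' Unestimable combinations (no data for a level combination under the
#' additive model) are dropped from the average with a warning.
#'
#' @param pheno phenotype data frame.
#' @param group line label to subset on (e.g. `"KR"`, `"LK"`, `"SUT"`).
#' @param response numeric response column (grams).
#' @param fixed fixed-effect factor columns.
#' @param group_col column holding the line label.
#' @return a list with `lsm` (grams, `NA` if the group is empty), `se`
#'   (`NA` when the residual variance is undefined, e.g. a single record)
#'   and `n` (records used).
#' @export
least_square_means <- function(pheno, group, response = "bw_g",
                               fixed = c("sex", "hatch"),
                               group_col = "line") {
  d <- as.data.frame(pheno)
  d <- d[!is.na(d[[response]]) & !is.na(d[[group_col]]) &
           d[[group_col]] == group, , drop = FALSE]
  if (nrow(d) == 0) {
    warning("no records for group '", group, "'; LSM is missing")
    return(list(lsm = NA_real_, se = NA_real_, n = 0L))
  }
  fixed <- intersect(fixed, names(d))
  keep <- character(0)
  for (f in fixed) {
    d[[f]] <- droplevels(factor_first_appearance(d[[f]]))
    if (nlevels(d[[f]]) >= 2) keep <- c(keep, f)
  }
  form <- stats::reformulate(if (length(keep)) keep else "1",
                             response = response)
  fit <- stats::lm(form, data = d)
  b <- stats::coef(fit)

  grid <- unique(d[keep])
  if (!length(keep)) grid <- data.frame(row.names = 1L)
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                            data = grid, xlev = fit$xlevels)
  est_cols <- !is.na(b)
  estimable <- rowSums(abs(mm[, !est_cols, drop = FALSE])) == 0
  if (!all(estimable))
    warning(sum(!estimable),
            " unestimable fixed-effect combination(s) dropped from the LSM")
  mm <- mm[estimable, est_cols, drop = FALSE]
  cbar <- colMeans(mm)
  lsm <- as.numeric(cbar %*% b[est_cols])

  se <- NA_real_
  if (fit$df.residual >= 1 && is.finite(stats::sigma(fit))) {
    V <- stats::vcov(fit)
    se <- sqrt(max(as.numeric(t(cbar) %*% V %*% cbar), 0))
  }
  list(lsm = lsm, se = se, n = nrow(d))
}

#' Midparent heterosis percentage
#'
#' `H% = 100 * (LSM_cross - midparent) / midparent` with
#' `midparent = (LSM_sire_line + LSM_dam_line) / 2`. Any missing input
#' propagates to a missing result (e.g. ages at which the parental lines
#' were not weighed).
#'
#' @param lsm_kr least-square mean of the crossbred line (grams).
#' @param lsm_lk,lsm_sut least-square means of the sire and dam lines.
#' @return heterosis in percent, or `NA` if any input is missing.
#' @export
heterosis_percent <- function(lsm_kr, lsm_lk, lsm_sut) {
  if (any(is.na(c(lsm_kr, lsm_lk, lsm_sut)))) return(NA_real_)
  mp <- (lsm_lk + lsm_sut) / 2
  if (mp <= 0) stop("midparent mean must be positive")
  100 * (lsm_kr - mp) / mp
}

#' Per-age heterosis table
#'
#' For each age, computes descriptive statistics of the crossbred body
#' weight (n, mean, CV%, min, max), the least-square means of the cross and
#' both parental lines (sex and hatch fixed), and the midparent heterosis
#' percentage. Ages at which a parental line has no records yield `NA`
#' heterosis.
#'
#' @param pheno phenotype data frame with columns `animal`, `line`,
#'   `age_wk`, the response, and the fixed factors.
#' @param response numeric response column.
#' @param fixed fixed-effect factor columns for the LSMs.
#' @param cross,sire_line,dam_line line labels.
#' @param ages ages to report (default: all observed, sorted).
#' @return a data frame with one row per age: `age_wk`, `n`, `mean`,
#'   `cv_pct`, `min`, `max`, `lsm_kr`, `lsm_lk`, `lsm_sut`,
#'   `heterosis_pct`.
#' @export
heterosis_table <- function(pheno, response = "bw_g",
                            fixed = c("sex", "hatch"),
                            cross = "KR", sire_line = "LK", dam_line = "SUT",
                            ages = NULL) {
  d <- as.data.frame(pheno)
  if (is.null(ages)) ages <- sort(unique(d$age_wk))
  rows <- lapply(ages, function(a) {
    da <- d[d$age_wk == a, , drop = FALSE]
    ykr <- da[[response]][da$line == cross & !is.na(da[[response]])]
    lkr <- suppressWarnings(
      least_square_means(da, cross, response, fixed))
    llk <- suppressWarnings(
      least_square_means(da, sire_line, response, fixed))
    lsu <- suppressWarnings(
      least_square_means(da, dam_line, response, fixed))
    data.frame(
      age_wk = a,
      n = length(ykr),
      mean = if (length(ykr)) mean(ykr) else NA_real_,
      cv_pct = if (length(ykr) > 1 && mean(ykr) != 0)
        100 * stats::sd(ykr) / mean(ykr) else NA_real_,
      min = if (length(ykr)) min(ykr) else NA_real_,
      max = if (length(ykr)) max(ykr) else NA_real_,
      lsm_kr = lkr$lsm, lsm_lk = llk$lsm, lsm_sut = lsu$lsm,
      heterosis_pct = heterosis_percent(lkr$lsm, llk$lsm, lsu$lsm)
    )
  })
  do.call(rbind, rows)
}
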