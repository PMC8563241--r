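#' Model specification for the animal model
#'
#' Describes the response and the fixed-effect factors of the
#' additive-plus-dominance animal model `y = Xb + Za + Wd + e`. The random
#' structure (additive effect with covariance `A * sigma2_a`, dominance with
#' `D * sigma2_d`, residual `I * sigma2_e`) is supplied to [reml_estimate()]
#' as relationship matrices.
#'
#' @param response name of the response column (grams).
#' @param fixed character vector of fixed-effect factor columns, in order.
#' @param age_wk optional age in weeks; if given and the phenotype table has
#'   an `age_wk` column, records are restricted to that age.
#' @return a list of class `kr_model_spec`.
#' @export
model_spec <- function(response = "bw_g", fixed = c("sex", "hatch"),
                       age_wk = NULL) {
  structure(list(response = response, fixed = fixed, age_wk = age_wk),
            class = "kr_model_spec")
}

#' Build design matrices for the animal model
#'
#' Constructs `y`, the fixed-effect incidence `X` (reference-level dummy
#' coding, factor levels ordered by first appearance), and the animal
#' incidence matrices `Z` (additive) and `W` (dominance). Every record row
#' has exactly one 1 in `Z` and in `W`; animals without records get all-zero
#' columns and still receive BLUPs through the relationship structure.
#' Fixed factors observed at a single level are dropped from `X` (they are
#' confounded with the intercept).
#'
#' @param pheno phenotype data frame with columns `animal`, the response, and
#'   the fixed-effect factors.
#' @param ped a `kr_pedigree` covering every animal with records.
#' @param spec a [model_spec()].
#' @return a list of class `kr_design` with `y`, `X`, `record_animal`
#'   (column index of each record's animal), `animal_ids`, and metadata.
#' @export
build_design_matrices <- function(pheno, ped, spec = model_spec()) {
  stopifnot(inherits(ped, "kr_pedigree"), inherits(spec, "kr_model_spec"))
  d <- as.data.frame(pheno)
  if (!is.null(spec$age_wk) && "age_wk" %in% names(d))
    d <- d[d$age_wk == spec$age_wk, , drop = FALSE]
  if (!spec$response %in% names(d))
    stop("response column '", spec$response, "' not found in phenotype table")
  d <- d[!is.na(d[[spec$response]]), , drop = FALSE]
  if (nrow(d) < 1) stop("no phenotype records to fit")
  d$animal <- trimws(as.character(d$animal))
  idx <- match(d$animal, ped$animal)
  if (anyNA(idx))
    stop("phenotype records reference animals absent from the pedigree: ",
         paste(utils::head(unique(d$animal[is.na(idx)]), 5), collapse = ", "))

  miss <- setdiff(spec$fixed, names(d))
  if (length(miss))
    stop("fixed-effect column(s) not found: ", paste(miss, collapse = ", "))
  keep <- character(0)
  for (f in spec$fixed) {
    d[[f]] <- factor_first_appearance(d[[f]])
    if (nlevels(droplevels(d[[f]])) >= 2) keep <- c(keep, f)
    d[[f]] <- droplevels(d[[f]])
  }
  form <- if (length(keep)) stats::reformulate(keep) else ~1
  X <- stats::model.matrix(form, data = d)
  if (qr(X)$rank < ncol(X))
    stop("fixed effects are confounded (X is rank-deficient): ",
         paste(keep, collapse = ", "))

  structure(list(
    y = as.numeric(d[[spec$response]]),
    X = X,
    record_animal = idx,
    animal_ids = ped$animal,
    fixed_used = keep,
    response = spec$response,
    age_wk = spec$age_wk,
    n = nrow(d),
    n_animals = nrow(ped)
  ), class = "kr_design")
}

# Dense incidence matrix mapping records to animals (one 1 per row).
incidence_matrix <- function(dm) {
  Z <- matrix(0, dm$n, dm$n_animals,
              dimnames = list(NULL, dm$animal_ids))
  Z[cbind(seq_len(dm$n), dm$record_animal)] <- 1
  Z
}
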