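#' Monte-Carlo gene-dropping estimate of relationship matrices
#'
#' Drops two distinct founder alleles per founder through the pedigree by
#' Mendelian sampling and estimates, for every pair of animals, the additive
#' relationship (twice the probability that randomly drawn alleles are
#' identical by descent) and the dominance relationship (the probability that
#' both alleles of one animal are IBD to both alleles of the other). This is
#' an oracle for [additive_relationship_matrix()] and
#' [dominance_relationship_matrix()]: it shares no code with the tabular
#' recursions.
#'
#' Note the realized diagonal differs from the closed-form conventions: the
#' additive diagonal estimates `1 + F_i` only in expectation, and the
#' dominance diagonal is fixed at 1 for comparability.
#'
#' @param ped a topologically ordered `kr_pedigree`.
#' @param n_reps number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a list of class `kr_gene_drop` with elements `additive`,
#'   `dominance` (estimated matrices), `se_additive`, `se_dominance`
#'   (entrywise Monte-Carlo standard errors) and `n_reps`.
#' @export
gene_drop_relationships <- function(ped, n_reps, seed = 1L) {
  stopifnot(inherits(ped, "kr_pedigree"))
  if (!is.numeric(n_reps) || n_reps < 1) stop("n_reps must be >= 1")
  n_reps <- as.integer(n_reps)
  if (!is_topologically_ordered(ped))
    stop("pedigree is not topologically ordered; call topological_order() first")
  ids <- ped$animal
  si <- match(ped$sire, ids); si[is.na(si)] <- 0L
  di <- match(ped$dam, ids);  di[is.na(di)] <- 0L

  raw <- with_seed(seed, gene_drop_cpp(as.integer(si), as.integer(di), n_reps))

  symmetrize <- function(U) {
    U[lower.tri(U)] <- t(U)[lower.tri(U)]
    dimnames(U) <- list(ids, ids)
    U
  }
  add_mean <- symmetrize(raw$add_sum / n_reps)
  add_var <- symmetrize(
    pmax(raw$add_sumsq / n_reps - (raw$add_sum / n_reps)^2, 0))
  se_add <- sqrt(add_var * n_reps / max(n_reps - 1, 1)) / sqrt(n_reps)
  dom_p <- symmetrize(raw$dom_sum / n_reps)
  se_dom <- sqrt(dom_p * (1 - dom_p) / n_reps)
  # dominance diagonal is 1 by convention (self pair is trivially IBD-matched)
  diag(dom_p) <- 1
  diag(se_dom) <- 0

  structure(list(additive = add_mean, dominance = dom_p,
                 se_additive = se_add, se_dominance = se_dom,
                 n_reps = n_reps, seed = seed),
            class = "kr_gene_drop")
}
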