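# Small pedigrees built in code, used across test files.

trio_ped <- function() {
  as_pedigree(data.frame(
    animal = c("s", "d", "o"),
    sire = c(NA, NA, "s"),
    dam = c(NA, NA, "d"),
    stringsAsFactors = FALSE))
}

fullsib_ped <- function(n_sibs = 2) {
  as_pedigree(data.frame(
    animal = c("s", "d", paste0("o", seq_len(n_sibs))),
    sire = c(NA, NA, rep("s", n_sibs)),
    dam = c(NA, NA, rep("d", n_sibs)),
    stringsAsFactors = FALSE))
}

# offspring of a full-sib mating: F = 0.25, diagonal 1.25
fullsib_mating_ped <- function() {
  as_pedigree(data.frame(
    animal = c("gs", "gd", "f1", "f2", "x"),
    sire = c(NA, NA, "gs", "gs", "f1"),
    dam = c(NA, NA, "gd", "gd", "f2"),
    stringsAsFactors = FALSE))
}

# double first cousins: parents are two full-sib pairs
double_cousin_ped <- function() {
  as_pedigree(data.frame(
    animal = c("a", "b", "c", "d", "s1", "s2", "d1", "d2", "x", "y"),
    sire = c(NA, NA, NA, NA, "a", "a", "c", "c", "s1", "s2"),
    dam = c(NA, NA, NA, NA, "b", "b", "d", "d", "d1", "d2"),
    stringsAsFactors = FALSE))
}

# Random valid pedigree: founders first, then offspring whose parents are
# drawn among earlier animals (sex roles ignored; the relationship algebra
# does not use them). Returned topologically ordered by construction.
rand_ped <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  n <- n_founders + n_offspring
  ids <- sprintf("a%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1):n) {
    pair <- sample(i - 1L, 2L)
    sire[i] <- ids[pair[1]]
    dam[i] <- ids[pair[2]]
  }
  as_pedigree(data.frame(animal = ids, sire = sire, dam = dam,
                         stringsAsFactors = FALSE))
}

# Random non-inbred pedigree: mates are always pairs with zero additive
# relationship (tracked incrementally), so no individual is inbred. This is
# the regime in which the classical dominance-relationship formula is exact,
# hence the right test bed for comparing D against gene dropping.
rand_nonbred_ped <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  n <- n_founders + n_offspring
  ids <- sprintf("a%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  A <- diag(n)
  for (i in (n_founders + 1):n) {
    prev <- seq_len(i - 1L)
    pr <- NULL
    for (k in 1:50) {
      cand <- sample(prev, 2L)
      if (A[cand[1], cand[2]] == 0) {
        pr <- cand
        break
      }
    }
    if (is.null(pr)) next  # crowded pedigree: add an extra founder instead
    sire[i] <- ids[pr[1]]
    dam[i] <- ids[pr[2]]
    A[i, prev] <- A[prev, i] <- 0.5 * (A[prev, pr[1]] + A[prev, pr[2]])
  }
  as_pedigree(data.frame(animal = ids, sire = sire, dam = dam,
                         stringsAsFactors = FALSE))
}

quiet_reml <- function(...) suppressWarnings(reml_estimate(...))

# simulation config for a small LK x SUT cross with all effects switched off
# except what the test sets
null_cfg <- function(..., seed = 1) {
  args <- list(...)
  defaults <- list(
    n_sires = 10, n_dams = 20, n_offspring_per_mating = 4,
    sigma2_a = 0, sigma2_d = 0, sigma2_e = 1,
    mu = 0, line_mean_offsets = c(LK = 0, SUT = 0, KR = 0),
    sex_effects = c(M = 0, F = 0),
    hatch_effects = c(H1 = 0, H2 = 0, H3 = 0),
    seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, args))
}
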