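test_that("simulated cross pedigrees have the right structure", {
  ped <- simulate_pedigree(null_cfg(n_sires = 2, n_dams = 2,
                                    n_offspring_per_mating = 1))
  expect_equal(nrow(ped), 6L)
  kr <- ped[ped$line == "KR", ]
  expect_equal(nrow(kr), 2L)
  expect_true(all(ped$line[match(kr$sire, ped$animal)] == "LK"))
  expect_true(all(ped$line[match(kr$dam, ped$animal)] == "SUT"))
  expect_true(is_female <- all(ped$sex[match(kr$dam, ped$animal)] == "F"))
  expect_error(simulation_config(n_sires = 0), "founder")
})

test_that("simulation output is bit-reproducible for a fixed seed", {
  cfg <- null_cfg(n_sires = 4, n_dams = 6, n_offspring_per_mating = 2,
                  sigma2_a = 10, sigma2_d = 5, sigma2_e = 5, seed = 31)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_pedigree(s1$pedigree, f1)
  write_pedigree(s2$pedigree, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("multi-generation pedigrees stay ordered with consistent labels", {
  ped <- simulate_pedigree(null_cfg(n_generations = 5, n_sires = 5,
                                    n_dams = 7, n_offspring_per_mating = 2))
  expect_identical(topological_order(ped)$animal, ped$animal)
  gen <- ped$generation
  pgen <- gen[match(ped$sire, ped$animal)]
  expect_true(all(pgen < gen, na.rm = TRUE))
  expect_true(all(ped$generation[ped$line == "KR"] == 5))
})

test_that("marker transmission follows the mating-design genotype groups", {
  make_cross <- function(sire_g, dam_g, n = 400) {
    ped <- as_pedigree(data.frame(
      animal = c("s", "d", paste0("o", seq_len(n))),
      sire = c(NA, NA, rep("s", n)), dam = c(NA, NA, rep("d", n)),
      line = c("LK", "SUT", rep("KR", n)), stringsAsFactors = FALSE))
    fg <- data.frame(animal = c("s", "d"),
                     gh_genotype = c(sire_g$gh, dam_g$gh),
                     igf1_genotype = c(sire_g$igf1, dam_g$igf1))
    simulate_marker_genotypes(ped, null_cfg(seed = 13),
                              founder_genotypes = fg)[-(1:2), ]
  }
  # homozygote x opposite homozygote -> all heterozygous offspring
  g <- make_cross(list(gh = "A1A1", igf1 = "CC"),
                  list(gh = "A3A3", igf1 = "AA"))
  expect_true(all(g$gh_genotype == "A1A3"))
  expect_true(all(g$igf1_genotype == "AC"))
})

test_that("heterozygote x heterozygote segregates 1:2:1", {
  n <- 10000
  ped <- as_pedigree(data.frame(
    animal = c("s", "d", paste0("o", seq_len(n))),
    sire = c(NA, NA, rep("s", n)), dam = c(NA, NA, rep("d", n)),
    stringsAsFactors = FALSE))
  fg <- data.frame(animal = c("s", "d"), gh_genotype = c("A1A3", "A1A3"),
                   igf1_genotype = c("AC", "AC"))
  g <- simulate_marker_genotypes(ped, null_cfg(seed = 14),
                                 founder_genotypes = fg)[-(1:2), ]
  counts <- table(factor(g$gh_genotype, c("A1A1", "A1A3", "A3A3")))
  expected <- n * c(0.25, 0.5, 0.25)
  se <- sqrt(n * c(0.25, 0.5, 0.25) * (1 - c(0.25, 0.5, 0.25)))
  expect_true(all(abs(counts - expected) <= 3 * se))
})

test_that("founders without a genotype assignment are an error", {
  ped <- as_pedigree(data.frame(animal = c("f1", "f2", "o"),
                                sire = c(NA, NA, "f1"),
                                dam = c(NA, NA, "f2"),
                                line = c("other", "other", "KR")))
  expect_error(simulate_marker_genotypes(ped, null_cfg()),
               "no genotype assignment")
})

test_that("genetic effects have the covariance their variances imply", {
  ped <- fullsib_ped()
  A <- additive_relationship_matrix(ped)
  D <- dominance_relationship_matrix(ped, A)
  cfg <- null_cfg(sigma2_a = 0, sigma2_d = 40)
  expect_identical(simulate_genetic_effects(ped, A, D, cfg)$a, rep(0, 4))

  # replicate draws: cov(d_o1, d_o2) / sigma2_d estimates the dominance
  # relationship of full sibs (0.25)
  reps <- 20000
  dmat <- matrix(0, reps, 2)
  for (r in seq_len(reps)) {
    cfg$seed <- r
    tr <- simulate_genetic_effects(ped, A, D, cfg)
    dmat[r, ] <- tr$d[3:4]
  }
  rho <- cov(dmat[, 1], dmat[, 2]) / 40
  se <- sqrt((1 + 0.25^2) / reps)  # var of a correlation-type estimator
  expect_lte(abs(rho - 0.25), 3 * se)

  # marginal variance matches sigma2_a times the mean diagonal
  cfg2 <- null_cfg(n_sires = 20, n_dams = 50, n_offspring_per_mating = 8,
                   sigma2_a = 100, seed = 15)
  sim <- simulate_dataset(cfg2, markers = FALSE)
  expect_lt(abs(var(sim$truth$a) / (100 * mean(diag(unclass(sim$A)))) - 1),
            0.25)
})

test_that("phenotypes decompose exactly into their simulated pieces", {
  cfg <- null_cfg(n_sires = 3, n_dams = 5, n_offspring_per_mating = 2,
                  sigma2_e = 0, mu = 43)
  sim <- simulate_dataset(cfg, markers = FALSE)
  expect_true(all(sim$phenotypes$bw_g == 43))

  cfg2 <- null_cfg(n_sires = 30, n_dams = 100, n_offspring_per_mating = 9,
                   sigma2_e = 25, sex_effects = c(M = 10, F = 0), seed = 16)
  sim2 <- simulate_dataset(cfg2, markers = FALSE)
  kr <- sim2$phenotypes[sim2$phenotypes$line == "KR", ]
  diff_sex <- mean(kr$bw_g[kr$sex == "M"]) - mean(kr$bw_g[kr$sex == "F"])
  se <- 5 * sqrt(1 / sum(kr$sex == "M") + 1 / sum(kr$sex == "F"))
  expect_lte(abs(diff_sex - 10), 3 * se)
})

test_that("marker effects create detectable genotype signal", {
  cfg <- null_cfg(n_sires = 20, n_dams = 60, n_offspring_per_mating = 6,
                  sigma2_e = 25,
                  marker_effects = list(gh = c(add = 10, dom = 3)),
                  seed = 17)
  sim <- simulate_dataset(cfg)
  kr <- sim$phenotypes[sim$phenotypes$line == "KR", ]
  ge <- genotype_effect(kr$bw_g, kr$gh_genotype, sex = kr$sex)
  expect_lt(ge$overall_p, 1e-4)
})

test_that("a written dataset reads back identically", {
  cfg <- null_cfg(n_sires = 3, n_dams = 4, n_offspring_per_mating = 2,
                  sigma2_e = 9, seed = 18)
  sim <- simulate_dataset(cfg)
  dir <- tempfile()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("ped.csv", "pheno.csv",
                                               "truth.csv")))))
  ped2 <- read_pedigree(file.path(dir, "ped.csv"))
  expect_equal(as.data.frame(ped2)[c("animal", "sire", "dam", "line")],
               as.data.frame(sim$pedigree)[c("animal", "sire", "dam",
                                             "line")])
  ph2 <- read_phenotypes(file.path(dir, "pheno.csv"))
  expect_equal(ph2$bw_g, sim$phenotypes$bw_g, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
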