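# Shared small simulated dataset: 4 sires x 8 dams x 3 offspring (+parents),
# all animals phenotyped.
mm_fixture <- function(seed = 21, sigma2_a = 50, sigma2_d = 30,
                       sigma2_e = 40) {
  cfg <- null_cfg(n_sires = 4, n_dams = 8, n_offspring_per_mating = 3,
                  sigma2_a = sigma2_a, sigma2_d = sigma2_d,
                  sigma2_e = sigma2_e, mu = 100,
                  sex_effects = c(M = 5, F = -5), seed = seed)
  sim <- simulate_dataset(cfg, markers = FALSE)
  ped <- sim$pedigree
  A <- additive_relationship_matrix(ped)
  D <- dominance_relationship_matrix(ped, A)
  dm <- build_design_matrices(sim$phenotypes, ped,
                              model_spec(fixed = c("sex", "line")))
  list(sim = sim, ped = ped, A = A, D = D, dm = dm)
}

test_that("REML matches an independent error-contrast oracle", {
  fx <- mm_fixture()
  vc <- quiet_reml(fx$dm, fx$A, fx$D)
  pieces <- oracle_pieces(fx$dm, fx$A, fx$D)
  ll_at <- function(th) kcontrast_loglik(pmax(th, 1e-10), pieces$y,
                                         pieces$X, pieces$Ga, pieces$Gd)
  opt <- optim(rep(var(pieces$y) / 3, 3), function(th) -ll_at(th),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  # our maximizer must be at least as good as the oracle's, under the
  # oracle's own likelihood
  expect_gte(ll_at(c(vc$sigma2_a, vc$sigma2_d, vc$sigma2_e)),
             -opt$value - 1e-4)
})

test_that("likelihood ascends and components stay in the simplex", {
  fx <- mm_fixture(seed = 22)
  vc <- quiet_reml(fx$dm, fx$A, fx$D)
  expect_true(all(diff(vc$loglik_trace) >= 0))
  expect_gte(vc$sigma2_a, 0)
  expect_gte(vc$sigma2_d, 0)
  expect_gt(vc$sigma2_e, 0)
  expect_equal(vc$sigma2_p, vc$sigma2_a + vc$sigma2_d + vc$sigma2_e)
  expect_lte(vc$h2 + vc$d_ratio, 1 + 1e-12)
  expect_gte(vc$h2, 0)
})

test_that("components pin to exact zero when the boundary is optimal", {
  cfg <- null_cfg(n_sires = 10, n_dams = 30, n_offspring_per_mating = 8,
                  sigma2_e = 100, seed = 5)
  sim <- simulate_dataset(cfg, markers = FALSE)
  ped <- sim$pedigree
  A <- additive_relationship_matrix(ped)
  D <- dominance_relationship_matrix(ped, A)
  ph <- sim$phenotypes
  # remove more than the full family mean: negative sib resemblance, so the
  # restricted likelihood is maximized at sigma2_a = sigma2_d = 0
  fam <- paste(ped$sire, ped$dam)[match(ph$animal, ped$animal)]
  ph$bw_g <- ph$bw_g - 1.3 * ave(ph$bw_g, fam)
  dm <- build_design_matrices(ph, ped, model_spec(fixed = "sex"))
  vc <- quiet_reml(dm, A, D)
  expect_identical(vc$sigma2_a, 0)
  expect_identical(vc$sigma2_d, 0)
  expect_identical(vc$h2, 0)
  expect_true(vc$converged)
  expect_true(all(diff(vc$loglik_trace) >= 0))
})

test_that("dropping the dominance term reproduces an additive-only fit", {
  fx <- mm_fixture(seed = 23, sigma2_d = 0)
  vc <- quiet_reml(fx$dm, fx$A, NULL, random = "additive")
  expect_identical(vc$sigma2_d, 0)
  pieces <- oracle_pieces(fx$dm, fx$A)
  ll_at <- function(th) kcontrast_loglik(pmax(th, 1e-10), pieces$y,
                                         pieces$X, pieces$Ga)
  opt <- optim(rep(var(pieces$y) / 2, 2), function(th) -ll_at(th),
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_gte(ll_at(c(vc$sigma2_a, vc$sigma2_e)), -opt$value - 1e-4)
  # and the oracle optimum is reproduced componentwise
  expect_equal(vc$sigma2_a, opt$par[1], tolerance = 0.02)
  expect_equal(vc$sigma2_e, opt$par[2], tolerance = 0.02)
})

test_that("variance components are scale-equivariant", {
  fx <- mm_fixture(seed = 24)
  vc1 <- quiet_reml(fx$dm, fx$A, fx$D)
  dm2 <- fx$dm
  dm2$y <- 10 * dm2$y
  vc2 <- quiet_reml(dm2, fx$A, fx$D)
  expect_equal(vc2$sigma2_a, 100 * vc1$sigma2_a, tolerance = 1e-6)
  expect_equal(vc2$sigma2_d, 100 * vc1$sigma2_d, tolerance = 1e-6)
  expect_equal(vc2$sigma2_e, 100 * vc1$sigma2_e, tolerance = 1e-6)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-6)
  expect_equal(vc2$d_ratio, vc1$d_ratio, tolerance = 1e-6)
})

test_that("hitting max_iter reports non-convergence loudly", {
  fx <- mm_fixture(seed = 25)
  expect_warning(vc <- reml_estimate(fx$dm, fx$A, fx$D, max_iter = 2L),
                 "did not converge")
  expect_false(vc$converged)
  expect_equal(vc$n_iter, 2L)
})

test_that("genetic parameter derivation handles ratios and degenerate input", {
  gp <- genetic_parameters(10, 10, 10)
  expect_equal(gp$h2, 1 / 3)
  expect_equal(gp$d_ratio, 1 / 3)
  expect_equal(gp$sigma2_p, 30)
  gp0 <- genetic_parameters(0, 0, 0)
  expect_true(is.na(gp0$h2))
  expect_true(is.na(gp0$d_ratio))
  expect_error(genetic_parameters(-1, 0, 1), ">= 0")
  # vectorized over ages, report layer rounds to 2 decimals
  gpv <- genetic_parameters(c(10, 20), c(0, 5), c(30, 15))
  expect_equal(gpv$sigma2_p, c(40, 40))
  expect_equal(format_genetic_parameters(gpv)$h2, c(0.25, 0.50))
})

test_that("MME solutions are self-consistent and respect dropped blocks", {
  fx <- mm_fixture(seed = 26)
  vc <- quiet_reml(fx$dm, fx$A, fx$D)
  vc$sigma2_a <- max(vc$sigma2_a, 10)  # ensure both blocks present
  vc$sigma2_d <- max(vc$sigma2_d, 10)
  sol <- solve_mme(fx$dm, fx$A, fx$D, vc)
  expect_lt(sol$solution_residual_norm, 1e-8)
  expect_equal(length(sol$a_hat), nrow(fx$ped))
  expect_equal(length(sol$d_hat), nrow(fx$ped))

  vc0 <- vc
  vc0$sigma2_d <- 0
  sol0 <- solve_mme(fx$dm, fx$A, fx$D, vc0)
  expect_identical(unname(sol0$d_hat), rep(0, nrow(fx$ped)))
  expect_lt(sol0$solution_residual_norm, 1e-8)

  vc_bad <- vc
  vc_bad$sigma2_e <- 0
  expect_error(solve_mme(fx$dm, fx$A, fx$D, vc_bad), "sigma2_e")
})

test_that("vanishing genetic variances recover the OLS fixed-effect fit", {
  fx <- mm_fixture(seed = 27)
  vc <- list(sigma2_a = 1e-8, sigma2_d = 1e-8, sigma2_e = 100)
  sol <- solve_mme(fx$dm, fx$A, fx$D, vc)
  ols <- qr.coef(qr(fx$dm$X), fx$dm$y)
  expect_equal(unname(sol$beta_hat), unname(ols), tolerance = 1e-6)
})

test_that("additive BLUPs track the simulated breeding values", {
  fx <- mm_fixture(seed = 28, sigma2_a = 80, sigma2_d = 0, sigma2_e = 20)
  vc <- quiet_reml(fx$dm, fx$A, NULL, random = "additive")
  sol <- solve_mme(fx$dm, fx$A, fx$D,
                   list(sigma2_a = max(vc$sigma2_a, 1),
                        sigma2_d = 0, sigma2_e = max(vc$sigma2_e, 1)))
  truth <- fx$sim$truth$a[match(names(sol$a_hat), fx$sim$truth$animal)]
  expect_gt(cor(sol$a_hat, truth), 0.6)
})
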