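test_that("max_iter = 0 returns the starting values with their likelihood", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  p0 <- default_start(sp, bank)
  sim <- sim_fixture(sp, p0, bank, n = 30, seed = 1)
  fit <- fit_baem(sim$data, sp, bank, start = p0,
                  control = proirt_control(quadpts = 11, max_iter = 0, se = FALSE))
  expect_identical(fit$estimate, pack_params(p0, sp, bank))
  expect_equal(fit$minus2LL,
               -2 * marginal_loglik(sim$data, sp, bank, p0,
                                    proirt_control(quadpts = 11)))
})

test_that("EM recovers growth-model means from simulated data", {
  bank <- synthetic_sleep_bank()
  sp <- growth_spec(3)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.3, -0.5)
  truth$Sigma[] <- matrix(c(0.15, 0.07, 0.07, 0.05), 2)
  sim <- sim_fixture(sp, truth, bank, n = 500, seed = 1)
  fit <- fit_baem(sim$data, sp, bank,
                  control = proirt_control(quadpts = 9, max_iter = 350))
  expect_equal(fit$convergence$status, "converged")
  # generating means recovered within 3 standard errors
  z <- abs(fit$estimate[1:2] - c(1.3, -0.5)) / fit$se[1:2]
  expect_true(all(z < 3))
})

test_that("EM is monotone to quadrature precision on a finely gridded fixture", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  p <- default_start(sp, bank)
  p$mu[] <- c(1.0, 0.4)
  sim <- sim_fixture(sp, p, bank, n = 60, seed = 11)
  fit <- fit_baem(sim$data, sp, bank,
                  control = proirt_control(quadpts = 31, max_iter = 150,
                                           se = FALSE))
  expect_true(all(diff(fit$convergence$loglik_trace) > -1e-8))
})

test_that("dispersed starting values reach the same solution", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.1, 0.5)
  sim <- sim_fixture(sp, truth, bank, n = 100, seed = 21)
  ctl <- proirt_control(quadpts = 13, max_iter = 500, tol = 5e-5, se = FALSE)
  s1 <- default_start(sp, bank)
  s2 <- default_start(sp, bank)
  s2$mu[] <- c(-1, 2); s2$Sigma[] <- diag(2) * 2; s2$s[] <- 0.3
  f1 <- fit_baem(sim$data, sp, bank, start = s1, control = ctl)
  f2 <- fit_baem(sim$data, sp, bank, start = s2, control = ctl)
  expect_lt(abs(f1$minus2LL - f2$minus2LL), 2e-4)
  # score norm small at the solution
  eng <- proirt:::make_engine(sim$data, sp, bank, ctl)
  expect_lt(max(abs(proirt:::fisher_score(eng, f1$params))), 1e-2)
})

test_that("Richardson differentiation recovers a quadratic's curvature exactly", {
  set.seed(5)
  A <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  v0 <- rnorm(4)
  gfun <- function(v) -drop(A %*% (v - v0))   # gradient of -(v-v0)'A(v-v0)/2
  H <- proirt:::richardson_hessian(gfun, v0 + rnorm(4), h0 = 1e-3)
  expect_equal(-H, A, tolerance = 1e-6)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  bank <- small_bank(4, 3)
  sp <- two_tier_spec(4, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.0, 0.5)
  ses <- lapply(c(120, 480), function(n) {
    sim <- sim_fixture(sp, truth, bank, n = n, seed = 31)
    fit <- fit_baem(sim$data, sp, bank,
                    control = proirt_control(quadpts = 9, max_iter = 250))
    fit$se
  })
  ratio <- ses[[1]][1:5] / ses[[2]][1:5]   # means and covariance block
  expect_true(all(ratio > 1.3 & ratio < 3.1))   # ~ sqrt(480/120) = 2
})

test_that("fixed parameters have no slot in the estimate or SE vectors", {
  bank <- synthetic_sleep_bank()
  sp <- growth_spec(3)
  nm <- param_names(sp, bank)
  expect_length(nm, 5L)
  expect_false(any(grepl("^s\\.", nm)))    # growth has no free specific slopes
})

test_that("cumulative and direct occasion parameterizations agree with free covariance", {
  # latent-difference pattern with an unstructured covariance is a linear
  # reparameterization of the two-tier (direct) pattern: same maximum
  bank <- small_bank(3, 3)
  tt <- two_tier_spec(3, 2)
  ld <- latent_difference_spec(3, 2)
  ld$cov_struct <- "full"               # lift the zero-covariance constraint
  truth <- default_start(tt, bank)
  truth$mu[] <- c(1.2, 0.7)
  truth$Sigma[] <- matrix(c(0.8, 0.5, 0.5, 1.0), 2)
  sim <- sim_fixture(tt, truth, bank, n = 120, seed = 13)
  ctl <- proirt_control(quadpts = 13, max_iter = 600, tol = 5e-5, se = FALSE)
  f_tt <- fit_baem(sim$data, tt, bank, control = ctl)
  f_ld <- fit_baem(sim$data, ld, bank, control = ctl)
  expect_lt(abs(f_tt$minus2LL - f_ld$minus2LL), 2e-4)
  # and the difference-factor means map back to the occasion means
  mu_ld <- f_ld$params$mu
  expect_equal(unname(cumsum(mu_ld)), unname(f_tt$params$mu), tolerance = 5e-3)
})
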