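test_that("the same seed and configuration reproduce the fit bitwise", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.0, 0.5)
  sim <- sim_fixture(sp, truth, bank, n = 60, seed = 2)
  cfg <- mhrm_control(n_burnin = 50, n_stage1 = 50, n_stage2 = 200,
                      se_cycles = 50)
  f1 <- fit_mhrm(sim$data, sp, bank, seed = 9, config = cfg)
  f2 <- fit_mhrm(sim$data, sp, bank, seed = 9, config = cfg)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$se, f2$se)
})

test_that("complete-data score and information match numerical derivatives", {
  bank <- small_bank(3, 3)
  sp <- attach_regression(add_site_level(latent_difference_spec(3, 2)),
                          "Follow-up 1", "tx")
  p <- default_start(sp, bank)
  p$mu[] <- c(1.1, -0.4); diag(p$Sigma) <- c(0.6, 0.8)
  p$B["Follow-up 1", "tx"] <- -0.5; p$site_var <- 0.2
  des <- trial_design(sp, p, bank, n_sites = 12, size_range = c(2, 6),
                      target_n = 40, retention = c(1, 1),
                      missing_baseline = 0, seed = 4)
  sim <- simulate_trial(des)
  st <- proirt:::mh_setup(sim$data, sp, bank)
  set.seed(6)
  lat <- list(Th = matrix(rnorm(st$n * 2), st$n, 2),
              Xi = matrix(rnorm(st$n * 3), st$n, 3),
              thc = rnorm(st$n_sites) * 0.3)
  v0 <- pack_params(p, sp, bank)
  si <- proirt:::cd_score_info(st, lat, p)
  f <- function(v) proirt:::cd_loglik(st, lat, unpack_params(v, sp, bank))
  gnum <- vapply(seq_along(v0), function(j) {
    h <- 1e-6 * (1 + abs(v0[j]))
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    (f(vp) - f(vm)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(si$s - gnum) / (1 + abs(gnum))), 1e-5)
  Inum <- -proirt:::richardson_hessian(function(v) {
    vapply(seq_along(v0), function(j) {
      h <- 1e-6 * (1 + abs(v0[j]))
      vp <- v; vp[j] <- vp[j] + h
      vm <- v; vm[j] <- vm[j] - h
      (f(vp) - f(vm)) / (2 * h)
    }, numeric(1))
  }, v0, h0 = 1e-3)
  expect_lt(max(abs(si$I - Inum) / (1 + abs(Inum))), 1e-3)
})

test_that("the Metropolis sweep targets the correct latent posterior", {
  # one item, one occasion, specific slope 0: posterior over theta available
  # by quadrature; imputed chain means must agree within Monte-Carlo error
  b1 <- item_bank(list(graded_item("x", 2.0, c(2, 1, 0, -1), s = 0)))
  s1 <- two_tier_spec(1, 1)
  p1 <- default_start(s1, b1); p1$s[] <- 0
  y <- matrix(c(0L, 2L, 4L), 3, 1)
  td <- trial_data(y, paste0("s", 1:3), item_ids = "x", T = 1)
  pm <- posterior_moments(td, s1, b1, p1, proirt_control(quadpts = 61))
  st <- proirt:::mh_setup(td, s1, b1)
  set.seed(3)
  lat <- list(Th = matrix(0, 3, 1), Xi = matrix(0, 3, 1), thc = numeric(0))
  scales <- list(theta = 1, xi = 1, site = 1)
  for (i in 1:200) lat <- proirt:::mh_sweep(st, lat, p1, scales)
  draws <- matrix(0, 400, 3)
  for (i in 1:400) {
    lat <- proirt:::mh_sweep(st, lat, p1, scales)
    draws[i, ] <- lat$Th[, 1]
  }
  mc_se <- apply(draws, 2, sd) / sqrt(400 / 10)  # crude ESS deflation
  expect_true(all(abs(colMeans(draws) - pm$mean[, 1]) < 3 * mc_se))
})

test_that("BAEM and MH-RM agree on the same two-tier data", {
  bank <- small_bank(4, 4)
  sp <- two_tier_spec(4, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.1, 0.5)
  truth$Sigma[] <- matrix(c(0.8, 0.45, 0.45, 0.9), 2)
  truth$s[] <- c(0.9, 0.7, 1.0, 0.8)
  sim <- sim_fixture(sp, truth, bank, n = 200, seed = 17)
  fb <- fit_baem(sim$data, sp, bank,
                 control = proirt_control(quadpts = 13, max_iter = 400))
  fm <- fit_mhrm(sim$data, sp, bank, seed = 17,
                 config = mhrm_control(n_burnin = 100, n_stage1 = 100,
                                       n_stage2 = 800, se_cycles = 500))
  cmb <- sqrt(rowSums(cbind(fb$se^2, fm$se^2), na.rm = TRUE))
  expect_true(all(abs(fb$estimate - fm$estimate) <= 3 * cmb))
})

test_that("recursive standard errors are close to Richardson standard errors", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.0, 0.4)
  truth$Sigma[] <- matrix(c(0.9, 0.4, 0.4, 0.8), 2)
  truth$s[] <- c(0.9, 0.8, 1.0)
  sim <- sim_fixture(sp, truth, bank, n = 200, seed = 23)
  fm <- fit_mhrm(sim$data, sp, bank, seed = 23,
                 config = mhrm_control(se_cycles = 0))
  rich <- se_richardson(sim$data, sp, bank, fm$params,
                        control = proirt_control(quadpts = 13))
  rec <- se_recursive(fm, n_cycles = 1500, seed = 23)
  expect_lt(max(abs(rec$se / rich$se - 1)), 0.25)
  # stability: doubling the cycles moves the well-mixed structural SEs by
  # less than 10% (the weakly identified specific slopes are noisier; their
  # typical change stays below 10% as well)
  rec2 <- se_recursive(fm, n_cycles = 3000, seed = 23)
  relchg <- abs(rec2$se / rec$se - 1)
  expect_lt(max(relchg[1:5]), 0.10)
  expect_lt(median(relchg), 0.10)
})

test_that("stage-2 parameter trace contracts (Robbins-Monro)", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  truth <- default_start(sp, bank)
  truth$mu[] <- c(1.0, 0.5)
  sim <- sim_fixture(sp, truth, bank, n = 80, seed = 29)
  fm <- fit_mhrm(sim$data, sp, bank, seed = 29,
                 config = mhrm_control(n_burnin = 50, n_stage1 = 100,
                                       n_stage2 = 600, se_cycles = 0,
                                       tol = 0, keep_trace = TRUE))
  tr <- fm$trace[-seq_len(100), , drop = FALSE]   # stage 2 only
  third <- nrow(tr) %/% 3
  v_early <- apply(tr[seq_len(third), ], 2, var)
  v_late <- apply(tr[(nrow(tr) - third + 1):nrow(tr), ], 2, var)
  expect_lt(median(v_late / pmax(v_early, 1e-12)), 1)
})

test_that("Monte-Carlo marginal likelihood matches quadrature and scales", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  p <- default_start(sp, bank)
  p$mu[] <- c(0.8, 0.3)
  p$Sigma[] <- matrix(c(0.7, 0.4, 0.4, 0.9), 2)
  p$s[] <- c(0.7, 0.5, 0.9)
  sim <- sim_fixture(sp, p, bank, n = 60, seed = 1)
  llq <- -2 * marginal_loglik(sim$data, sp, bank, p, proirt_control(quadpts = 31))
  mc <- mc_marginal_loglik(sim$data, sp, bank, p, n_samples = 250, seed = 1)
  expect_length(mc$ci, 2L)
  expect_lt(mc$ci[1], mc$ci[2])
  expect_lt(abs(mc$minus2LL - llq), 4 * (diff(mc$ci) / 2))
  mc2 <- mc_marginal_loglik(sim$data, sp, bank, p, n_samples = 1000, seed = 1)
  expect_lt(diff(mc2$ci), diff(mc$ci))    # half-width shrinks with samples
  expect_error(mc_marginal_loglik(sim$data, sp, bank, p, n_samples = 10),
               "batches")
})
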