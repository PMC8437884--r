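test_that("the default design matches the emulated trial's shape", {
  sim <- simulate_trial(default_trial_design(seed = 3))
  d <- sim$data
  n <- nrow(d$Y)
  expect_gte(n, 240); expect_lte(n, 260)
  expect_equal(length(unique(d$site)), 67L)
  sizes <- table(d$site)
  expect_true(all(sizes >= 1 & sizes <= 12))
  expect_equal(d$T, 3L)
  expect_equal(d$K, 8L)
  # monotone dropout roughly follows the retention schedule
  obs <- vapply(1:3, function(t)
    sum(rowSums(!is.na(d$Y[, (t - 1) * 8 + 1:8])) > 0), numeric(1))
  expect_true(all(diff(obs) <= 0))
  expect_gt(obs[2] / obs[1], 0.90)
  expect_gt(obs[3] / obs[1], 0.85)
  # one late-enrolled subject: baseline missing, later visits observed
  bl_missing <- rowSums(!is.na(d$Y[, 1:8])) == 0
  later <- rowSums(!is.na(d$Y[, 9:24])) > 0
  expect_gte(sum(bl_missing & later), 1L)
  # manifest records a generating value for every free parameter
  des <- default_trial_design(seed = 3)
  expect_setequal(names(sim$manifest$truth),
                  param_names(des$spec, des$bank))
})

test_that("a null treatment effect leaves the arms equal in expectation", {
  bank <- synthetic_sleep_bank()
  sp <- attach_regression(latent_difference_spec(8, 3), "Follow-up 1", "tx")
  p <- default_start(sp, bank)
  p$mu[] <- c(1.4, -0.8, -0.2)
  diag(p$Sigma) <- c(0.5, 0.8, 0.3)
  p$B[, "tx"] <- 0
  des <- trial_design(sp, p, bank, n_sites = 1, size_range = c(2000, 2000),
                      target_n = 2000, retention = rep(1, 3),
                      missing_baseline = 0, seed = 12)
  sim <- simulate_trial(des, keep_latents = TRUE)
  tx <- sim$data$covariates$tx
  for (g in 1:3) {
    d <- mean(sim$latents$theta[tx == 1, g]) - mean(sim$latents$theta[tx == 0, g])
    se <- sqrt(var(sim$latents$theta[, g]) * (1 / sum(tx) + 1 / sum(1 - tx)))
    expect_lt(abs(d), 3 * se)
  }
})

test_that("simulated site effects reproduce the target intraclass correlation", {
  bank <- small_bank(2, 3)
  sp <- add_site_level(latent_difference_spec(2, 2))
  p <- default_start(sp, bank)
  p$mu[] <- c(1.4, -0.5)
  diag(p$Sigma) <- c(0.47, 0.3)
  p$site_var <- 0.17
  des <- trial_design(sp, p, bank, n_sites = 500, size_range = c(10, 10),
                      target_n = 5000, retention = c(1, 1),
                      missing_baseline = 0, seed = 15)
  sim <- simulate_trial(des, keep_latents = TRUE)
  # baseline composite = baseline difference factor + site effect
  site_part <- sim$latents$site_effect[sim$latents$site_of]
  v_b <- var(sim$latents$theta[, 1])
  v_s <- var(site_part)
  icc_hat <- v_s / (v_s + v_b)
  # 3 x Monte-Carlo SE of an ICC at 500 clusters is roughly 0.03
  expect_lt(abs(icc_hat - icc(0.17, 0.47)), 0.03)
})

test_that("two-tier generating means produce declining severity scores", {
  bank <- synthetic_sleep_bank()
  tt <- two_tier_truth(bank)
  des <- trial_design(tt$spec, tt$params, bank, n_sites = 1,
                      size_range = c(400, 400), target_n = 400,
                      retention = rep(1, 3), missing_baseline = 0, seed = 19)
  sim <- simulate_trial(des)
  tmeans <- vapply(1:3, function(t) {
    mean(eap_score(sim$data$Y[, (t - 1) * 8 + 1:8], bank)$t_score)
  }, numeric(1))
  expect_true(all(diff(tmeans) < 0))   # improvement concentrated early
  expect_gt(tmeans[1] - tmeans[2], tmeans[2] - tmeans[3])
})

test_that("designs validate their inputs", {
  bank <- synthetic_sleep_bank()
  sp <- latent_difference_spec(8, 3)
  p <- default_start(sp, bank)
  expect_error(trial_design(sp, p, bank), "seed")
  expect_error(trial_design(sp, p, bank, allocation = c(0.7, 0.6), seed = 1),
               "sum to 1")
  expect_error(trial_design(sp, p, bank, retention = c(1, 1), seed = 1),
               "length")
})

test_that("simulate() from a fit preserves the design and missingness", {
  bank <- small_bank(3, 3)
  sp <- two_tier_spec(3, 2)
  truth <- default_start(sp, bank)
  sim <- sim_fixture(sp, truth, bank, n = 40, seed = 22)
  fit <- fit_baem(sim$data, sp, bank, start = truth,
                  control = proirt_control(quadpts = 11, max_iter = 5,
                                           se = FALSE))
  rep1 <- simulate(fit, seed = 5)
  expect_identical(is.na(rep1$Y), is.na(sim$data$Y))
  expect_identical(rep1$subject, sim$data$subject)
  expect_false(identical(rep1$Y, sim$data$Y))
})
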