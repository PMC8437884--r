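test_that("dimension reduction matches brute-force quadrature (oracle)", {
  bank2 <- small_bank(2, 3)
  set.seed(1)
  # 2 items, 1 occasion: 1 general + 2 specific factors (3 dimensions)
  sp1 <- two_tier_spec(2, 1)
  Y1 <- matrix(sample(0:2, 15 * 2, replace = TRUE), 15, 2)
  td1 <- trial_data(Y1, paste0("s", 1:15), item_ids = c("i1", "i2"), T = 1)
  p1 <- default_start(sp1, bank2)
  p1$mu[] <- 0.4; p1$Sigma[] <- 0.8
  ctl <- proirt_control(quadpts = 11)
  expect_equal(marginal_loglik(td1, sp1, bank2, p1, ctl),
               marginal_loglik(td1, sp1, bank2, p1, ctl, method = "naive"),
               tolerance = 1e-10)
  # 2 items, 2 occasions: 2 generals + 2 specifics (4 dimensions)
  sp2 <- two_tier_spec(2, 2)
  Y2 <- matrix(sample(0:2, 12 * 4, replace = TRUE), 12, 4)
  td2 <- trial_data(Y2, paste0("s", 1:12), item_ids = c("i1", "i2"), T = 2)
  p2 <- default_start(sp2, bank2)
  p2$mu[] <- c(0.6, 0.2)
  p2$Sigma[] <- matrix(c(0.9, 0.4, 0.4, 0.7), 2)
  expect_equal(marginal_loglik(td2, sp2, bank2, p2, ctl),
               marginal_loglik(td2, sp2, bank2, p2, ctl, method = "naive"),
               tolerance = 1e-10)
  # growth with 2 occasions: intercept + slope + 2 occasion residuals
  g2 <- growth_spec(2)
  pg <- default_start(g2, bank2)
  pg$mu[] <- c(0.8, -0.3); pg$Sigma[] <- matrix(c(0.4, 0.1, 0.1, 0.2), 2)
  expect_equal(marginal_loglik(td2, g2, bank2, pg, ctl),
               marginal_loglik(td2, g2, bank2, pg, ctl, method = "naive"),
               tolerance = 1e-10)
})

test_that("conditional independence: conditional loglik adds per item", {
  bank2 <- small_bank(2, 3)
  sp <- two_tier_spec(2, 1)
  p <- default_start(sp, bank2)
  y <- c(1L, 2L)
  both <- conditional_loglik(y, sp, bank2, p, theta = 0.5, xi = c(0.2, -0.4))
  one <- conditional_loglik(c(1L, NA), sp, bank2, p, theta = 0.5,
                            xi = c(0.2, -0.4))
  two <- conditional_loglik(c(NA, 2L), sp, bank2, p, theta = 0.5,
                            xi = c(0.2, -0.4))
  expect_equal(both, one + two)
  expect_equal(conditional_loglik(c(NA, NA), sp, bank2, p, theta = 0.5,
                                  xi = c(0, 0)), 0)
  # one item, s = 0: log of the single category probability
  b1 <- item_bank(list(graded_item("x", 2, c(1, -1), s = 0)))
  s1 <- two_tier_spec(1, 1)
  p1 <- default_start(s1, b1); p1$s[] <- 0
  expect_equal(conditional_loglik(1L, s1, b1, p1, theta = 0.3, xi = 0),
               unname(log(category_prob(b1$items[[1]], 0.3, 0, 1))))
})

test_that("grid refinement converges and the likelihood is layout-invariant", {
  bank <- small_bank(4, 4)
  sp <- two_tier_spec(4, 3)
  p <- default_start(sp, bank)
  p$mu[] <- c(1.2, 0.6, 0.3); p$s[] <- 0.8
  sim <- sim_fixture(sp, p, bank, n = 60, seed = 5)
  ll <- vapply(c(9, 15, 31), function(q)
    marginal_loglik(sim$data, sp, bank, p, proirt_control(quadpts = q)),
    numeric(1))
  expect_lt(abs(ll[2] - ll[3]), abs(ll[1] - ll[3]))

  # subject-order invariance
  d <- sim$data
  set.seed(2)
  perm <- sample(nrow(d$Y))
  dp <- trial_data(d$Y[perm, ], d$subject[perm], d$site[perm],
                   d$covariates[perm, , drop = FALSE], d$item_ids, d$T)
  ctl <- proirt_control(quadpts = 11)
  expect_equal(marginal_loglik(dp, sp, bank, p, ctl),
               marginal_loglik(d, sp, bank, p, ctl), tolerance = 1e-12)

  # wide <-> block conversion invariance
  fb <- tempfile(fileext = ".csv")
  write_trial(d, fb, "block")
  db <- read_trial_block(fb)
  expect_equal(marginal_loglik(db, sp, bank, p, ctl),
               marginal_loglik(d, sp, bank, p, ctl), tolerance = 1e-12)

  # all-missing data contributes zero
  dempty <- trial_data(matrix(NA_integer_, 3, 12), paste0("e", 1:3),
                       item_ids = bank_ids(bank), T = 3)
  expect_equal(marginal_loglik(dempty, sp, bank, p, ctl), 0)
})

test_that("the multilevel likelihood approaches the single-level one as the site variance vanishes", {
  bank <- small_bank(3, 3)
  sp0 <- latent_difference_spec(3, 2)
  p0 <- default_start(sp0, bank)
  p0$mu[] <- c(1.0, -0.5); p0$s[] <- 0.7
  sim <- sim_fixture(sp0, p0, bank, n = 40, seed = 3)
  sps <- add_site_level(latent_difference_spec(3, 2))
  ctl <- proirt_control(quadpts = 11, site_quadpts = 7)
  ll0 <- marginal_loglik(sim$data, sp0, bank, p0, ctl)
  dif <- vapply(c(1e-6, 1e-8, 1e-10), function(v) {
    ps <- default_start(sps, bank)
    ps$mu[] <- p0$mu; ps$Sigma[] <- p0$Sigma; ps$s[] <- p0$s
    ps$site_var <- v
    abs(marginal_loglik(sim$data, sps, bank, ps, ctl) - ll0)
  }, numeric(1))
  expect_true(all(diff(dif) < 0))
  expect_lt(dif[3], 1e-6)
})

test_that("the analytic marginal score matches numerical differentiation", {
  bank <- small_bank(3, 3)
  sp <- attach_regression(two_tier_spec(3, 2), "Follow-up 1", "tx")
  p <- default_start(sp, bank)
  p$mu[] <- c(0.9, 0.4); p$Sigma[] <- matrix(c(0.8, 0.3, 0.3, 0.9), 2)
  p$s[] <- c(0.8, 0.6, 0.9); p$B["Follow-up 1", "tx"] <- -0.4
  sim <- sim_fixture(sp, p, bank, n = 80, seed = 7)
  ctl <- proirt_control(quadpts = 21)
  eng <- proirt:::make_engine(sim$data, sp, bank, ctl)
  v0 <- pack_params(p, sp, bank)
  g_ana <- proirt:::fisher_score(eng, p)
  g_num <- vapply(seq_along(v0), function(j) {
    h <- 1e-5 * (1 + abs(v0[j]))
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    (proirt:::engine_estep(eng, unpack_params(vp, sp, bank))$loglik -
       proirt:::engine_estep(eng, unpack_params(vm, sp, bank))$loglik) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g_ana - g_num) / (1 + abs(g_num))), 5e-3)
})

test_that("posterior moments behave like Bayesian updates", {
  b1 <- item_bank(list(graded_item("x", 2.0, c(2, 1, 0, -1))))
  s1 <- two_tier_spec(1, 1)
  p1 <- default_start(s1, b1); p1$s[] <- 0
  ctl <- proirt_control(quadpts = 31)
  eaps <- vapply(0:4, function(cc) {
    td <- trial_data(matrix(cc, 1, 1), "s1", item_ids = "x", T = 1)
    posterior_moments(td, s1, b1, p1, ctl)$mean[1, 1]
  }, numeric(1))
  expect_true(all(diff(eaps) > 0))           # monotone in the response
  td <- trial_data(matrix(2L, 1, 1), "s1", item_ids = "x", T = 1)
  pm <- posterior_moments(td, s1, b1, p1, ctl)
  expect_lt(pm$cov[1, 1, 1], 1)              # shrinkage below the prior
  tdm <- trial_data(matrix(NA_integer_, 1, 1), "s1", item_ids = "x", T = 1)
  pmm <- posterior_moments(tdm, s1, b1, p1, ctl)
  expect_equal(pmm$mean[1, 1], 0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pmm$cov[1, 1, 1], 1, tolerance = 0.01)
})
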