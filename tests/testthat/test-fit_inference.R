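test_that("information criteria identities hold", {
  expect_equal(unname(information_criteria(100, 0, 1)), c(100, 100))
  ic <- information_criteria(13334.19, 17, 250)
  expect_equal(unname(ic["AIC"]), 13368.19, tolerance = 1e-9)
  expect_equal(unname(ic["BIC"]), 13428.06, tolerance = 0.011)
  ic2 <- information_criteria(13810.51, 5, 250)
  expect_equal(round(unname(ic2), 2), c(13820.51, 13838.12))
})

test_that("Wald tests compute the chi-square of linear hypotheses", {
  # estimate equal to the hypothesis: W = 0, p = 1
  v <- c(a = 1, b = -2)
  V <- diag(c(0.04, 0.09))
  w0 <- wald_test(v, V, L = diag(2), h = c(1, -2))
  expect_equal(w0$W, 0)
  expect_equal(w0$p_value, 1)
  # one-parameter test is the squared z ratio
  w1 <- wald_test(c(b = -0.56), matrix(0.01), L = matrix(1))
  expect_equal(w1$W, 31.36, tolerance = 1e-9)
  expect_equal(w1$df, 1L, ignore_attr = TRUE)
  # omnibus treatment test in a 5-arm design has 4 df
  set.seed(8)
  p <- 10
  est <- rnorm(p)
  V <- crossprod(matrix(rnorm(p * p), p)) / p + diag(p) * 0.1
  L <- matrix(0, 4, p); L[cbind(1:4, 3:6)] <- 1
  w4 <- wald_test(est, V, L)
  expect_equal(w4$df, 4L, ignore_attr = TRUE)
  # invariance to nonsingular reparameterization of the contrast rows
  R <- matrix(c(2, 1, 0, 0,  0, 1, 3, 0,  0, 0, 1, 0,  1, 0, 0, 2), 4, 4)
  wR <- wald_test(est, V, R %*% L)
  expect_equal(wR$W, w4$W, tolerance = 1e-8)
  # singular L V L' falls back to a generalized inverse with reduced df
  Ls <- rbind(L[1, ], L[1, ])
  expect_warning(ws <- wald_test(est, V, Ls), "singular")
  expect_equal(ws$df, 1L, ignore_attr = TRUE)
})

test_that("covariance-to-correlation standardization matches hand values", {
  V <- matrix(c(0.73, 0.33, 0.28,
                0.33, 0.96, 0.89,
                0.28, 0.89, 1.13), 3)
  r <- cov_to_corr(V)
  expect_equal(round(r[1, 2], 2), 0.39)
  expect_equal(round(r[1, 3], 2), 0.31)
  expect_equal(round(r[2, 3], 2), 0.85)
  expect_equal(cov_to_corr(diag(3)), diag(3))
  expect_equal(cov_to_corr(matrix(c(4, 3, 3, 9), 2))[1, 2], 0.5)
  expect_error(cov_to_corr(matrix(c(0, 0, 0, 1), 2)), "diagonal")
})

test_that("intraclass correlation composes variance components", {
  expect_equal(round(icc(0.17, 0.47), 2), 0.27)
  expect_equal(icc(0, 2), 0)
  expect_equal(icc(3, 3), 0.5)
  expect_error(icc(0, 0), "positive")
})

test_that("M2 is calibrated under the generating model", {
  bank <- small_bank(4, 3)
  sp <- two_tier_spec(4, 2)
  p <- default_start(sp, bank)
  p$mu[] <- c(0.9, 0.4)
  p$Sigma[] <- matrix(c(0.8, 0.5, 0.5, 1.0), 2)
  p$s[] <- c(0.8, 0.6, 0.9, 0.7)
  sim <- sim_fixture(sp, p, bank, n = 1000, seed = 9)
  m2 <- m2_rmsea(data = sim$data, spec = sp, bank = bank, params = p,
                 control = proirt_control(quadpts = 15))
  # under the null, M2 ~ chi-square(df): RMSEA is small (truncates to 0 when
  # M2 <= df) and the p-value is not extreme
  expect_lt(m2$RMSEA, 0.03)
  expect_gt(m2$p_value, 1e-4)
  expect_equal(m2$df, m2$n_margins - n_free_params(sp, 4))
  # misfit raises the statistic: evaluate at wrong parameters
  pbad <- p
  pbad$mu[] <- c(-0.5, 1.5)
  m2b <- m2_rmsea(data = sim$data, spec = sp, bank = bank, params = pbad,
                  control = proirt_control(quadpts = 15))
  expect_gt(m2b$RMSEA, m2$RMSEA)
  expect_gt(m2b$RMSEA, 0.05)
})

test_that("M2 guards its preconditions", {
  bank <- small_bank(3, 3)
  sps <- add_site_level(two_tier_spec(3, 2))
  expect_error(m2_rmsea(data = NULL, spec = sps, bank = bank,
                        params = default_start(sps, bank)),
               "single-level")
  bank8 <- synthetic_sleep_bank()
  sp8 <- two_tier_spec(8, 3)
  d8 <- trial_data(matrix(2L, 20, 24), paste0("s", 1:20),
                   item_ids = bank_ids(bank8), T = 3)
  expect_error(m2_rmsea(data = d8, spec = sp8, bank = bank8,
                        params = default_start(sp8, bank8),
                        max_margins = 100), "cap")
})
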