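test_that("growth specs use the latent curve basis", {
  g <- growth_spec(3)
  expect_equal(unname(g$A), cbind(c(1, 1, 1), c(0, 1, 2)))
  expect_equal(n_free_params(g), 5L)   # 2 means + 2 variances + 1 covariance
  g2 <- growth_spec(2)
  expect_equal(unname(g2$A), cbind(c(1, 1), c(0, 1)))
  expect_error(growth_spec(1), "at least 2")
  expect_error(growth_spec(3, time_codes = c(0, 1)), "length")
})

test_that("two-tier pattern has banked general and shared specific loadings", {
  bank <- synthetic_sleep_bank()
  tt <- two_tier_spec(8, 3)
  L <- loading_pattern(tt, bank)
  expect_equal(dim(L), c(24L, 11L))
  expect_equal(sum(L != 0), 48L)          # one general + one specific per row
  expect_equal(n_free_params(tt), 17L)    # 3 means + 6 cov + 8 slopes
  # specific slope constrained equal over occasions
  expect_equal(L["t1_item1", "spec_item1"], L["t3_item1", "spec_item1"])
  # general loadings fixed at the banked values
  expect_equal(unname(L["t2_item1", "Follow-up 1"]), 3.39)

  small <- loading_pattern(two_tier_spec(1, 2), item_bank(list(
    graded_item("only", 1.5, c(1, -1)))))
  expect_equal(dim(small), c(2L, 3L))
  expect_equal(small[1, 3], small[2, 3])
})

test_that("latent-difference pattern is cumulative with uncorrelated factors", {
  bank <- synthetic_sleep_bank()
  ld <- latent_difference_spec(8, 3)
  L <- loading_pattern(ld, bank)
  expect_equal(sum(L != 0), 72L)          # 8 + 16 + 24 general + 24 specific
  expect_equal(n_free_params(ld), 14L)    # 3 means + 3 variances + 8 slopes
  expect_equal(ld$cov_struct, "diagonal")
  # occasion t loads on general factors 1..t
  expect_equal(unname(L["t3_item1", 1:3]), rep(3.39, 3))
  expect_equal(unname(L["t1_item1", 2:3]), c(0, 0))
  # one occasion reduces to the two-tier pattern
  L1 <- loading_pattern(latent_difference_spec(8, 1), bank)
  L2 <- loading_pattern(two_tier_spec(8, 1), bank)
  expect_equal(unname(L1), unname(L2))
})

test_that("site level and regressions extend the spec correctly", {
  sp <- latent_difference_spec(8, 3)
  sp <- add_site_level(sp)
  expect_equal(sp$site$loadings, rep(1, 3))
  expect_error(add_site_level(sp), "already")
  expect_equal(n_free_params(sp), 15L)
  sp <- attach_regression(sp, "Follow-up 1", "tx")
  expect_equal(n_free_params(sp), 16L)
  expect_true("beta.Follow-up 1.tx" %in% param_names(sp))
  expect_error(attach_regression(sp, "nonesuch", "tx"), "unknown factor")
  expect_equal(integration_dimension(sp), 5L)
})

test_that("parameter packing round-trips exactly for every spec", {
  bank <- small_bank(4, 4)
  specs <- list(
    growth_spec(3),
    growth_spec(3, level = "block"),
    two_tier_spec(4, 3),
    attach_regression(add_site_level(latent_difference_spec(4, 3)),
                      "Baseline", "tx"))
  set.seed(42)
  for (sp in specs) {
    p0 <- default_start(sp, bank)
    v0 <- pack_params(p0, sp, bank)
    expect_equal(length(v0), n_free_params(sp, 4))
    # random feasible values survive unpack/pack
    v <- v0 + stats::runif(length(v0), -0.05, 0.05)
    expect_identical(pack_params(unpack_params(v, sp, bank), sp, bank),
                     stats::setNames(v, names(v0)))
  }
})

test_that("integration dimension reflects two-tier reduction", {
  expect_equal(integration_dimension(two_tier_spec(8, 3)), 4L)
  expect_equal(integration_dimension(growth_spec(3)), 3L)
  expect_equal(integration_dimension(growth_spec(3, level = "block")), 3L)
  expect_equal(integration_dimension(add_site_level(latent_difference_spec(8, 3))), 5L)
})
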