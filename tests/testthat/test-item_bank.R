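test_that("cumulative and category probabilities follow the graded model", {
  it <- graded_item("i1", 2.0, c(1.0, -1.0))
  # boundaries required for consistency
  expect_equal(cumulative_prob(it, 1.7, 0.3, 0), 1)
  expect_equal(cumulative_prob(it, 1.7, 0.3, 3), 0)
  # frozen logistic evaluations
  expect_equal(cumulative_prob(it, 0, 0, 1), 0.731059, tolerance = 1e-6)
  expect_equal(category_prob(it, 0, 0, 1), 0.462117, tolerance = 1e-6)
  expect_error(cumulative_prob(it, 0, 0, 4), "category")
  expect_error(category_prob(it, 0, 0, 3), "category")
})

test_that("category probabilities form a proper distribution and are monotone", {
  it <- graded_item("k", 2.3, c(2, 0.5, -0.7, -2.1), s = 0.9)
  for (eta in c(-3, -0.5, 0, 1.4, 3)) for (xi in c(-2, 0, 2)) {
    p <- vapply(0:4, function(cc) category_prob(it, eta, xi, cc), numeric(1))
    expect_true(all(p >= 0) && all(p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    cum <- vapply(0:5, function(cc) cumulative_prob(it, eta, xi, cc), numeric(1))
    expect_true(all(diff(cum) <= 0))
  }
  # strictly increasing in eta for interior categories
  etas <- seq(-4, 4, by = 0.5)
  for (cc in 1:4)
    expect_true(all(diff(cumulative_prob(it, etas, 0, cc)) > 0))
})

test_that("a zero specific slope makes probabilities independent of xi", {
  it <- graded_item("k", 2.0, c(1, -1), s = 0)
  for (cc in 0:2)
    expect_identical(category_prob(it, 0.7, -3, cc),
                     category_prob(it, 0.7, 3, cc))
})

test_that("the banked 8-item fixture behaves like a calibrated short form", {
  bank <- synthetic_sleep_bank()
  expect_length(bank, 8)
  expect_equal(vapply(bank$items, `[[`, numeric(1), "a_star"),
               c(3.39, 2.58, 2.80, 2.51, 2.30, 2.47, 2.37, 2.77),
               ignore_attr = TRUE)
  # top category probability approaches 1 for very high severity
  expect_gt(category_prob(bank$items[[1]], 50, 0, 4), 1 - 1e-10)
})

test_that("item and bank validation reject malformed input", {
  expect_error(graded_item("x", 2, c(-1, 1)), "decreasing")
  expect_error(graded_item("x", -1, c(1, -1)), "positive")
  expect_error(graded_item("x", 1, c(1, -1), s = -0.5), "non-negative")
  g <- graded_item("dup", 1, c(1, -1))
  expect_error(item_bank(list(g, g)), "duplicate")
})

test_that("bank files round-trip and honour the declared parameterization", {
  bank <- synthetic_sleep_bank()
  f <- tempfile(fileext = ".csv")
  write_item_bank(bank, f)
  b2 <- read_item_bank(f)
  expect_equal(bank_ids(b2), bank_ids(bank))
  expect_equal(bank_slopes(b2), bank_slopes(bank))
  expect_equal(bank_intercepts(b2), bank_intercepts(bank))
  expect_identical(attr(b2, "category_base"), 1L)

  # difficulty-parameterized file: logit = a (eta - b)  =>  c = -a b
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("# parameterization: difficulty",
               "# category_base: 1",
               "item_id,n_categories,slope,intercept_1,intercept_2",
               "d1,3,2.0,-1.0,0.5"), f2)
  b3 <- read_item_bank(f2)
  expect_equal(b3$items[[1]]$c_star, c(2.0, -1.0))

  # nonmonotone intercepts are rejected at read time
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("# parameterization: intercept",
               "item_id,n_categories,slope,intercept_1,intercept_2",
               "bad,3,1.5,-1.0,1.0"), f3)
  expect_error(read_item_bank(f3), "decreasing")
})

test_that("the shipped fixture bank file loads", {
  f <- system.file("extdata", "synthetic_sleep_bank_8item.csv",
                   package = "proirt")
  bank <- read_item_bank(f)
  expect_length(bank, 8)
  expect_equal(unname(bank_slopes(bank)[1]), 3.39)
})
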