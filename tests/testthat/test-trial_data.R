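test_that("wide and block files round-trip through the readers", {
  des <- default_trial_design(seed = 8)
  sim <- simulate_trial(des)
  fw <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_trial(sim$data, fw, "wide")
  write_trial(sim$data, fb, "block")
  dw <- read_trial_wide(fw)
  db <- read_trial_block(fb)
  expect_identical(dw$Y, sim$data$Y)
  expect_identical(db$Y, sim$data$Y)
  expect_identical(db$covariates$tx, sim$data$covariates$tx)
  expect_identical(dw$site, sim$data$site)
  # wide -> block -> wide identity through the converters
  expect_identical(as_wide(db), as_wide(sim$data))
})

test_that("a subject missing at baseline parses with structural missingness", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# category_base: 1",
               "subject,site,tx,t1_item1,t1_item2,t2_item1,t2_item2",
               "A,1,0,2,3,1,2",
               "B,1,1,,,4,5",
               "C,2,0,1,1,,"), f)
  d <- read_trial_wide(f)
  expect_equal(nrow(d$Y), 3L)
  expect_true(all(is.na(d$Y[2, 1:2])))     # baseline missing, follow-up present
  expect_equal(d$Y[2, 3:4], c(3L, 4L), ignore_attr = TRUE)
  expect_true(all(is.na(d$Y[3, 3:4])))
})

test_that("validation catches malformed data", {
  expect_error(trial_data(matrix(0L, 2, 3), c("a", "b"),
                          item_ids = c("i1", "i2"), T = 2),
               "columns")
  expect_error(trial_data(matrix(0L, 2, 4), c("a", "a"),
                          item_ids = c("i1", "i2"), T = 2),
               "duplicate")
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject,site,occasion,i1,i2",
               "A,1,1,2,3",
               "A,1,1,1,2"), f)
  expect_error(read_trial_block(f), "duplicate")
})

test_that("category base offsets are honoured", {
  Y <- matrix(c(1L, 5L, 3L, 2L), 1)
  f <- tempfile(fileext = ".csv")
  writeLines(c("# category_base: 1",
               "subject,t1_i1,t1_i2,t2_i1,t2_i2",
               "A,1,5,3,2"), f)
  d <- read_trial_wide(f)
  expect_equal(d$Y[1, ], c(0L, 4L, 2L, 1L), ignore_attr = TRUE)
  expect_equal(unname(as.matrix(as_wide(d)[, -1])), Y)
})
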