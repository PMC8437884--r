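test_that("pattern EAP scoring is monotone and handles missing data", {
  bank <- synthetic_sleep_bank()
  allmiss <- eap_score(rep(NA_integer_, 8), bank)
  expect_equal(allmiss$theta, 0, tolerance = 1e-9)
  expect_equal(allmiss$sd, 1, tolerance = 1e-3)
  expect_true(allmiss$all_missing)
  # raising any single response never decreases the EAP
  base <- rep(2L, 8)
  e0 <- eap_score(base, bank)$theta
  for (k in 1:8) {
    up <- base; up[k] <- 3L
    expect_gte(eap_score(up, bank)$theta, e0)
  }
  lo <- eap_score(rep(0L, 8), bank)$theta
  hi <- eap_score(rep(4L, 8), bank)$theta
  expect_lt(lo, hi)
})

test_that("the summed-score table spans all sums with increasing EAPs", {
  bank <- synthetic_sleep_bank()
  tab <- summed_score_table(bank)
  expect_equal(nrow(tab), 33L)          # sums 8..40 on 1-based coding
  expect_equal(range(tab$sum), c(8L, 40L))
  expect_true(all(diff(tab$theta) > 0))
  expect_equal(tab$t_score, round(50 + 10 * tab$theta, 1))
})

test_that("a single-item bank makes summed and pattern scoring identical", {
  b1 <- item_bank(list(graded_item("x", 2.2, c(1.5, 0, -1.5))))
  tab <- summed_score_table(b1, category_base = 0)
  pat <- eap_score(matrix(0:3, 4, 1), b1)
  expect_equal(tab$theta, pat$theta, tolerance = 1e-12)
  expect_equal(tab$sd, pat$sd, tolerance = 1e-12)
})

test_that("the conversion table is invariant to item order", {
  bank <- synthetic_sleep_bank()
  rev_bank <- item_bank(rev(bank$items))
  t1 <- summed_score_table(bank)
  t2 <- summed_score_table(rev_bank)
  expect_equal(t1$theta, t2$theta, tolerance = 1e-12)
})

test_that("table EAPs sit inside the span of pattern EAPs at each sum", {
  b3 <- small_bank(3, 3)
  tab <- summed_score_table(b3, category_base = 0)
  pats <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  pe <- eap_score(pats, b3)$theta
  sums <- rowSums(pats)
  for (s in unique(sums)) {
    span <- range(pe[sums == s])
    te <- tab$theta[tab$sum == s]
    expect_gte(te, span[1] - 1e-9)
    expect_lte(te, span[2] + 1e-9)
  }
})

test_that("the T transform follows the bank metric", {
  expect_equal(t_score(0), 50)
  expect_equal(t_score(1), 60)
  expect_equal(t_score(1.34), 63.4)
  b <- item_bank(list(graded_item("x", 1, c(1, -1))), mean_T = 0, sd_T = 1)
  expect_equal(t_score(2, b), 2)
})
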