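test_that("flow-value error is the absolute percent deviation from Qref", {
  expect_equal(flow_value_error(100, 100), 0)
  expect_equal(flow_value_error(120, 100), 20)
  expect_equal(flow_value_error(80, 100), 20)
  expect_error(flow_value_error(100, 0), "positive")
})

test_that("repeatability error uses the test value as denominator", {
  expect_equal(round(repeatability_error(496, 479, signed = TRUE), 2), -3.43)
  expect_equal(repeatability_error(123.4, 123.4), 0)
  expect_equal(repeatability_error(100, 115), 15)
  # asymmetric in (test, retest): the denominator is the test session
  expect_false(isTRUE(all.equal(repeatability_error(100, 115),
                                repeatability_error(115, 100))))
  expect_error(repeatability_error(0, 10), "nonzero")
})

test_that("summary statistics use the sample (n-1) standard deviation", {
  s <- summary_stats(c(2, 4, 6))
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 2)
  expect_equal(s$n, 3L)
  one <- summary_stats(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
  expect_error(summary_stats(numeric(0)), "empty")
})

test_that("threshold counting is strict and monotone", {
  vals <- c(3, 15, 15.01, 40)
  expect_equal(count_exceeding(vals, 15), 2L)
  expect_equal(count_exceeding(numeric(0), 15), 0L)
  expect_equal(count_exceeding(c(1, 2), 15), 0L)
  thresholds <- c(0, 5, 15, 20, 50)
  counts <- vapply(thresholds, count_exceeding, values = vals, numeric(1L))
  expect_true(all(diff(counts) <= 0))
})

test_that("Bland-Altman limits bracket the mean difference symmetrically", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_difference, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  off <- bland_altman(c(1, 2, 3), c(0, 1, 2))
  expect_equal(off$mean_difference, 1)
  expect_equal(off$sd_difference, 0)
  expect_equal(c(off$loa_low, off$loa_high), c(1, 1))

  set.seed(4)
  a <- stats::runif(10); b <- stats::runif(10)
  expect_equal(bland_altman(a, b)$mean_difference,
               -bland_altman(b, a)$mean_difference)
  ba <- bland_altman(a, b)
  expect_lte(ba$loa_low, ba$mean_difference)
  expect_lte(ba$mean_difference, ba$loa_high)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("linear fit returns OLS slope/intercept and Pearson r", {
  f <- linear_fit(1:10, 1:10)
  expect_equal(c(f$slope, f$intercept, f$r), c(1, 0, 1))
  g <- linear_fit(1:10, 2 * (1:10) + 1)
  expect_equal(c(g$slope, g$intercept, g$r), c(2, 1, 1))
  set.seed(5)
  x <- stats::runif(20); y <- stats::rnorm(20, x)
  expect_equal(linear_fit(5 * x - 2, y)$r, linear_fit(x, y)$r)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
})

test_that("flow-meter QC compares Qcyl + Qtube against Qpump", {
  qc <- flowmeter_qc(31, 124, 150)
  expect_equal(qc$observed_percent, 100 * 5 / 150)
  expect_true(qc$passed)
  expect_equal(flowmeter_qc(70, 50, 120)$observed_percent, 0)
  # within the 15% limit but above 10%: flagged only at the tighter limit
  v <- flowmeter_qc(100, 122, 200)
  expect_equal(v$observed_percent, 11)
  expect_true(v$passed)
  expect_false(flowmeter_qc(100, 122, 200, limit_percent = 10)$passed)
  expect_error(flowmeter_qc(10, 10, 0), "positive")
})

test_that("activity QC enforces the dispenser tolerance", {
  qc <- activity_qc(431, 500)
  expect_equal(qc$observed_percent, 13.8)
  expect_true(qc$passed)
  expect_true(activity_qc(500, 500)$passed)
  boundary <- activity_qc(575.1, 500)
  expect_equal(boundary$observed_percent, 15.02)
  expect_false(boundary$passed)
})
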