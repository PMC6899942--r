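test_that("drift correction inverts a noiseless linear drift exactly", {
  t <- seq(0, 1000, by = 50)
  series <- data.frame(time = t, b = 0, signal = 100 * (1 - 1e-4 * t))
  # noiseless input: the slope t-test sits on an essentially perfect fit
  out <- suppressWarnings(drift_correct(series))
  expect_true(out$corrected)
  expect_lt(out$p_value, 0.05)
  expect_lt(diff(range(out$series$signal)) / mean(out$series$signal), 1e-6)
  # non-b0 rows are corrected with the same time-dependent factor
  series2 <- rbind(series,
                   data.frame(time = 210, b = 300,
                              signal = 40 * (1 - 1e-4 * 210)))
  out2 <- suppressWarnings(drift_correct(series2[order(series2$time), ]))
  expect_equal(out2$series$signal[out2$series$b == 300] * 100, 40,
               tolerance = 1e-6)
})

test_that("zero-slope series pass through unchanged", {
  withr::with_seed(8, {
    series <- data.frame(time = seq(0, 900, by = 100), b = 0,
                         signal = 100 + rnorm(10, 0, 1))
  })
  out <- drift_correct(series)
  expect_gt(out$p_value, 0.05)
  expect_false(out$corrected)
  expect_identical(out$series$signal, series$signal)
})

test_that("drift correction rejects degenerate input", {
  expect_error(drift_correct(data.frame(time = c(0, 1), b = 0,
                                        signal = c(1, 2))), "three")
  expect_error(drift_correct(data.frame(time = rep(5, 4), b = 0,
                                        signal = 1:4)), "degenerate")
})

test_that("wCV matches the hand-computed RMS example and is scale invariant", {
  expect_equal(wcv(c(10, 12, 20, 22), c(1, 1, 2, 2)), 10.26257,
               tolerance = 1e-5)
  expect_equal(wcv(7 * c(10, 12, 20, 22), c(1, 1, 2, 2)),
               wcv(c(10, 12, 20, 22), c(1, 1, 2, 2)))
  expect_equal(wcv(c(5, 5, 9, 9), c("a", "a", "b", "b")), 0)
  expect_error(wcv(c(1, 2), c(1, 1)), "two subjects")
  expect_error(wcv(c(-1, 1, 2, 3), c(1, 1, 2, 2)), "zero within-subject")
  # pooled variant: sqrt(mean within-variance) / grand mean
  expect_equal(wcv(c(10, 12, 20, 22), c(1, 1, 2, 2), method = "pooled"),
               100 * sqrt(2) / 16, tolerance = 1e-8)
})

test_that("ICC is 1 for perfect agreement and matches a hand ANOVA oracle", {
  perfect <- matrix(c(1, 2, 3, 4, 1, 2, 3, 4), ncol = 2)
  expect_equal(icc_agreement(perfect)$icc, 1)
  m <- matrix(c(9, 6, 8, 7, 8, 2, 4, 1), ncol = 2)
  # oracle: explicit sums of squares of the two-way layout
  n <- 4; k <- 2
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (msc - mse) / n)
  res <- icc_agreement(m)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_equal(res$k, 2)
})

test_that("large within-subject variability yields a negative ICC flagged n.a.", {
  m <- matrix(c(0.78, -0.11, -2.75, -0.83, 2.21, 2.88, 5.20, 4.53),
              ncol = 2)
  res <- icc_agreement(m)
  expect_lt(res$icc, 0)
  expect_equal(res$reliability, "n.a.")
})

test_that("ICC input validation rejects missing cells and tiny designs", {
  expect_error(icc_agreement(matrix(c(1, 2, NA, 4), 2)), "missing")
  expect_error(icc_agreement(matrix(1:4, 2)), "three subjects")
  expect_error(icc_agreement(matrix(1:3, 3)), "two occasions")
})

test_that("simulated two-way data recover the analytic ICC", {
  sig_s <- 1; sig_o <- 0.3; sig_e <- 0.5; n <- 20; k <- 3
  icc_true <- sig_s^2 / (sig_s^2 + (sig_o^2 + sig_e^2) / k)
  iccs <- withr::with_seed(15, replicate(200, {
    m <- outer(rnorm(n, 0, sig_s), rnorm(k, 0, sig_o), `+`) +
      matrix(rnorm(n * k, 0, sig_e), n, k)
    icc_agreement(m)$icc
  }))
  expect_lt(abs(mean(iccs) - icc_true), 0.05)
})

test_that("protocol bias follows the reference-minus-test convention", {
  expect_equal(protocol_bias(c(2, 2), c(2, 2)), 0)
  expect_equal(protocol_bias(2.0, 1.8), 10)
  expect_equal(protocol_bias(2.0, 2.2), -10)
  expect_error(protocol_bias(c(0, 1), c(1, 1)), "nonzero")
})

test_that("echo-time rescaling of f has the right fixed points and value", {
  expect_equal(t2_adjust_f(0.3, 80, 80), 0.3)
  expect_equal(t2_adjust_f(0.3, 122, 50, t2_tissue = 100, t2_blood = 100),
               0.3)
  f_adj <- t2_adjust_f(0.45, te_obs = 122, te_target = 50)
  expect_equal(round(100 * f_adj, 1), 20.3)
  expect_error(t2_adjust_f(1, 122, 50), "strictly")
  expect_error(t2_adjust_f(0.4, -5, 50))
})
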