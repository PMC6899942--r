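test_that("curve normalization scales to the mean b = 0 signal and is idempotent", {
  cv <- fcivim:::signal_curve(
    data.frame(b = c(0, 0, 100), T = 100, beta = 0,
               signal = c(90, 110, 50)))
  out <- normalize_curve(cv)
  expect_equal(out$signal, c(0.9, 1.1, 0.5))
  expect_equal(normalize_curve(out)$signal, out$signal)
  cv2 <- fcivim:::signal_curve(
    data.frame(b = c(0, 0, 50), T = 100, beta = 0, signal = c(2, 2, 1)))
  expect_equal(normalize_curve(cv2)$signal, c(1, 1, 0.5))
  cv3 <- fcivim:::signal_curve(
    data.frame(b = c(10, 50), T = 100, beta = 0, signal = c(1, 0.5)))
  expect_error(normalize_curve(cv3), "b = 0")
})

test_that("high-b mono-exponential initialization recovers D and f", {
  D <- 1.5e-3; f <- 0.2
  b <- c(0, 150, 250, 350, 450, 600)
  cv <- fcivim:::signal_curve(
    data.frame(b = b, T = 100, beta = 0,
               signal = (1 - f) * exp(-b * D) + f * (b == 0)),
    normalized = TRUE)
  init <- init_high_b(cv)
  expect_lt(abs(init[["D"]] - D) / D, 0.02)
  expect_lt(abs(init[["f"]] - f), 0.02)
})

test_that("initialization requires bipolar high-b data and handles f = 0", {
  cv_fc <- fcivim:::signal_curve(
    data.frame(b = c(0, 200, 400), T = 100, beta = 1,
               signal = c(1, 0.7, 0.5)))
  expect_error(init_high_b(cv_fc), "bipolar")
  b <- c(0, 150, 300, 500)
  cv0 <- fcivim:::signal_curve(
    data.frame(b = b, T = 100, beta = 0, signal = exp(-b * 1e-3)),
    normalized = TRUE)
  expect_lt(abs(init_high_b(cv0)[["f"]]), 1e-10)
})

test_that("noiseless parameter recovery is accurate on a rich scheme", {
  truth <- interior_truth()
  cv <- forward_signal(rich_scheme(), truth, tbl = phase_tbl())
  fit <- fcivim(cv, tbl = phase_tbl())
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est[["D"]] - truth[["D"]]) / truth[["D"]], 0.01)
  expect_lt(abs(est[["f"]] - truth[["f"]]) / truth[["f"]], 0.01)
  expect_lt(abs(est[["tau"]] - truth[["tau"]]) / truth[["tau"]], 0.05)
  expect_lt(abs(est[["v"]] - truth[["v"]]) / truth[["v"]], 0.05)
})

test_that("noiseless recovery holds across random interior truths", {
  tb <- phase_tbl()
  sc <- rich_scheme()
  errs <- withr::with_seed(42, {
    t(replicate(25, {
      tr <- tissue_params(runif(1, 1e-3, 2e-3), runif(1, 0.15, 0.4),
                          runif(1, 50, 400), runif(1, 2, 9))
      cv <- forward_signal(sc, tr, tbl = tb)
      est <- coef(fcivim(cv, tbl = tb))
      abs(normalized_errors(tr, est, "truth"))
    }))
  })
  expect_lt(median(errs[, "D"]), 1)
  expect_lt(median(errs[, "f"]), 1)
  expect_lt(median(errs[, "tau"]), 5)
  expect_lt(median(errs[, "v"]), 5)
})

test_that("the fit is invariant to overall curve scaling", {
  truth <- interior_truth()
  cv <- forward_signal(rich_scheme(), truth, tbl = phase_tbl())
  cv7 <- cv; cv7$signal <- cv7$signal * 7
  est1 <- coef(fcivim(cv, tbl = phase_tbl()))
  est7 <- coef(fcivim(cv7, tbl = phase_tbl()))
  expect_equal(est1, est7, tolerance = 1e-9)
})

test_that("estimates always respect the bounds on noisy curves", {
  tb <- phase_tbl()
  sc <- rich_scheme()
  bounds <- fit_bounds()
  lo <- fcivim:::bounds_lower(bounds); hi <- fcivim:::bounds_upper(bounds)
  withr::with_seed(7, {
    for (i in 1:40) {
      tr <- as.list(sample_tissue(tissue_ranges(), 1))
      cv <- forward_signal(sc, tissue_params(tr$D, tr$f, tr$tau, tr$v),
                           tbl = tb)
      cv <- add_rician(cv, snr_eff = 15)
      est <- coef(fcivim(cv, bounds = bounds, tbl = tb))
      expect_true(all(est >= lo - 1e-12 & est <= hi + 1e-12))
    }
  })
})

test_that("spleen organ bounds constrain D to its Table-style interval", {
  tb <- phase_tbl()
  sc <- rich_scheme()
  bounds <- organ_bounds("spleen")
  withr::with_seed(11, {
    for (i in 1:10) {
      cv <- forward_signal(sc, tissue_params(0.9e-3, 0.09, 150, 6), tbl = tb)
      cv <- add_rician(cv, snr_eff = 10)
      D <- coef(fcivim(cv, bounds = bounds, tbl = tb))[["D"]]
      expect_gte(D, 0.5e-3); expect_lte(D, 1.5e-3)
    }
  })
})

test_that("broadening bounds leaves noiseless interior recovery unchanged", {
  truth <- interior_truth()
  cv <- forward_signal(rich_scheme(), truth, tbl = phase_tbl())
  est_def <- coef(fcivim(cv, bounds = fit_bounds(), tbl = phase_tbl()))
  est_broad <- coef(fcivim(cv, bounds = fit_bounds("broad"),
                           tbl = phase_tbl()))
  expect_equal(est_def, est_broad, tolerance = 5e-3)
})

test_that("normalized errors follow the truth-minus-fit sign convention", {
  tr <- c(D = 1.5e-3, f = 0.25, tau = 260, v = 5.5)
  expect_equal(normalized_errors(tr, tr), c(D = 0, f = 0, tau = 0, v = 0))
  ft <- c(D = 1.65e-3, f = 0.25, tau = 234, v = 5.5)
  err <- normalized_errors(tr, ft, error_norms())
  expect_equal(err[["tau"]], 10)        # (260 - 234) / 260 * 100
  expect_equal(err[["D"]], -10)         # overestimate -> negative
})

test_that("degenerate schemes are rejected and non-convergence is reported", {
  cv <- fcivim:::signal_curve(
    data.frame(b = c(0, 10, 10, 0), T = 100, beta = 0,
               signal = c(1, 0.9, 0.9, 1)))
  expect_error(fcivim(cv), "identifiable")
  tr <- interior_truth()
  cv2 <- forward_signal(rich_scheme(), tr, tbl = phase_tbl())
  fit <- fcivim(cv2, tbl = phase_tbl(),
                control = minpack.lm::nls.lm.control(ftol = 1e-8,
                                                     maxiter = 1))
  expect_false(fit$converged)
  expect_match(fit$message, ".")
})

test_that("fcivim methods are coherent", {
  truth <- interior_truth()
  cv <- forward_signal(rich_scheme(), truth, tbl = phase_tbl())
  fit <- fcivim(cv, tbl = phase_tbl())
  expect_s3_class(fit, "fcivim")
  expect_equal(fitted(fit) + residuals(fit), fit$data$signal)
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(b = c(0, 100), T = 100, beta = 0)
  pr <- predict(fit, nd)
  expect_equal(pr[1], coef(fit)[["S0"]])
  sm <- summary(fit)
  expect_s3_class(sm, "summary.fcivim")
  expect_equal(nrow(sm$coefficients), 5)
  sims <- simulate(fit, nsim = 3, seed = 1, snr_eff = 30)
  expect_equal(dim(sims), c(nrow(fit$data), 3))
  expect_output(print(fit), "FC-IVIM")
})
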