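test_that("tissue sampling stays in range, reproduces, and centers correctly", {
  rg <- tissue_ranges()
  d1 <- withr::with_seed(3, sample_tissue(rg, 1e5))
  d2 <- withr::with_seed(3, sample_tissue(rg, 1e5))
  expect_identical(d1, d2)
  for (nm in c("D", "f", "tau", "v")) {
    expect_true(all(d1[[nm]] >= rg[[nm]][1] & d1[[nm]] <= rg[[nm]][2]))
  }
  # mean of U(20, 500) is 260 ms, the tau normalization constant
  expect_lt(abs(mean(d1$tau) - 260) / 260, 0.01)
  expect_error(tissue_ranges(D = c(2e-3, 1e-3)), "invalid")
})

test_that("Rician noise has the right scale and limits", {
  cv <- fcivim:::signal_curve(
    data.frame(b = 0, T = 100, beta = 0, signal = rep(1, 2e4)),
    normalized = TRUE)
  # effectively noiseless at huge SNR
  out <- withr::with_seed(1, add_rician(cv, snr_eff = 1e9))
  expect_lt(max(abs(out$signal - 1)), 1e-6)
  # Rayleigh mean for zero signal, sigma = 1, single direction
  cv0 <- fcivim:::signal_curve(
    data.frame(b = 0, T = 100, beta = 0, signal = rep(0, 1e6)),
    normalized = TRUE)
  ray <- withr::with_seed(2, add_rician(cv0, snr_eff = 1, n_directions = 1,
                                        snr_scope = "per_direction"))
  se <- sqrt(2 - pi / 2) / sqrt(1e6)
  expect_lt(abs(mean(ray$signal) - sqrt(pi / 2)), 3 * se)
  # direction-averaged b = 0 noise SD is 1/snr_eff
  avg <- withr::with_seed(3, add_rician(cv, snr_eff = 20, n_directions = 6))
  expect_lt(abs(sd(avg$signal) - 0.05) / 0.05, 0.05)
  expect_error(add_rician(cv, snr_eff = 0), "positive")
})

test_that("candidate grids contain only feasible points with the stated spacing", {
  grid <- candidate_grid()
  expect_gt(nrow(grid), 100)
  hw <- hardware_limits()
  for (i in seq_len(nrow(grid)))
    expect_lte(grid$b[i], max_b(grid$beta[i], grid$T[i], hw))
  # denser b spacing at low b than at high b
  bs <- sort(unique(grid$b))
  expect_lt(max(diff(bs[bs <= 40])), min(diff(bs[bs >= 200])))
  # finer T grid for FC than for bipolar
  expect_gt(length(unique(grid$T[grid$beta == 1])),
            length(unique(grid$T[grid$beta == 0])))
  expect_error(candidate_grid(config = grid_config(b = 5e4, b_cap = 1e5)),
               "excludes")
})

test_that("scheme cost is deterministic under a seed and small without noise", {
  tb <- phase_tbl()
  sc <- rich_scheme()
  c1 <- scheme_cost(sc, n_rep = 20, seed = 5, tbl = tb)
  c2 <- scheme_cost(sc, n_rep = 20, seed = 5, tbl = tb)
  expect_identical(as.numeric(c1), as.numeric(c2))
  # without noise the cost collapses for identifiable tissues (in the
  # deep diffusive corner of the range only tau * v^2 is identifiable,
  # so the noiseless cost does not vanish over the full range)
  rg <- tissue_ranges(tau = c(80, 300), v = c(2, 8))
  c0 <- scheme_cost(sc, ranges = rg, snr_eff = 1e7, n_rep = 10, seed = 9,
                    tbl = tb)
  expect_lt(as.numeric(c0), 1)
  c20 <- scheme_cost(sc, ranges = rg, snr_eff = 20, n_rep = 10, seed = 9,
                     tbl = tb)
  expect_lt(as.numeric(c0), 0.2 * as.numeric(c20))
})

test_that("averaging duplicate acquisitions lowers the expected cost", {
  tb <- phase_tbl()
  sc <- acquisition_scheme(b = c(0, 0, 20, 60, 100, 150, 300, 600),
                           T = c(100, 100, 100, 100, 40, 100, 100, 100),
                           beta = c(0, 1, 0, 1, 1, 1, 0, 0),
                           label = "toy8")
  dup <- acquisition_scheme(b = sc$b, T = sc$T, beta = sc$beta,
                            n_repeats = 2, label = "toy8x2")
  c1 <- scheme_cost(sc, n_rep = 200, seed = 21, tbl = tb)
  c2 <- scheme_cost(dup, n_rep = 200, seed = 21, tbl = tb)
  expect_lt(as.numeric(c2), as.numeric(c1))
})

test_that("one greedy step equals exhaustive recomputation with shared seed", {
  tb <- phase_tbl()
  base <- base_scheme()
  grid <- structure(data.frame(b = c(10, 30, 100, 300, 150),
                               T = c(100, 100, 100, 100, 40),
                               beta = c(0, 0, 1, 0, 1)),
                    class = c("candidate_grid", "data.frame"))
  des <- greedy_optimize(base, grid, n_add = 1, n_rep = 50, seed = 17,
                         tbl = tb)
  step_seed <- withr::with_seed(17,
    sample.int(.Machine$integer.max - 1L, 1))
  costs <- sapply(seq_len(nrow(grid)), function(i) {
    cand <- fcivim:::add_point(base, grid$b[i], grid$T[i], grid$beta[i])
    as.numeric(scheme_cost(cand, n_rep = 50, seed = step_seed, tbl = tb))
  })
  best <- which.min(costs)
  expect_equal(des$trace$b, grid$b[best])
  expect_equal(des$trace$T, grid$T[best])
  expect_equal(des$trace$beta, grid$beta[best])
  expect_equal(des$trace$cost, costs[best])
})

test_that("repeated selections bump the repeat count", {
  sc <- base_scheme()
  sc2 <- fcivim:::add_point(sc, 0, 100, 0)
  expect_equal(nrow(sc2), nrow(sc))
  expect_equal(sum(sc2$n_repeats), sum(sc$n_repeats) + 1)
})

test_that("scheme evaluation yields sorted percentiles and shrinks with SNR", {
  tb <- phase_tbl()
  sc <- rich_scheme()
  truth <- liver_literature()
  ev_lo <- evaluate_scheme(sc, truth, snr_eff = 10, n_rep = 60, seed = 5,
                           tbl = tb)
  ev_hi <- evaluate_scheme(sc, truth, snr_eff = 60, n_rep = 60, seed = 5,
                           tbl = tb)
  for (p in c("D", "f", "tau", "v")) {
    expect_false(is.unsorted(ev_lo$percentiles[, p]))
    spread_lo <- ev_lo$percentiles["p95", p] - ev_lo$percentiles["p5", p]
    spread_hi <- ev_hi$percentiles["p95", p] - ev_hi$percentiles["p5", p]
    expect_lt(spread_hi, spread_lo)
  }
})
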