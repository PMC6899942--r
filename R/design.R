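# Simulation-driven acquisition design: repeatedly add to the scheme the
# (b, T, beta) candidate that minimizes the mean normalized parameter error
# over random tissues and Rician noise realizations, sharing the random
# draws across all candidates within one greedy step.

#' Uniform tissue-parameter sampling ranges
#'
#' Defaults are typical abdominal values used during scheme optimization:
#' D 1-2e-3 mm^2/s, f 10-40\%, tau 20-500 ms, v 1-10 mm/s.
#'
#' @param D,f,tau,v `c(low, high)` uniform sampling intervals.
#' @return An object of class `tissue_ranges`.
#' @export
tissue_ranges <- function(D = c(1e-3, 2e-3), f = c(0.10, 0.40),
                          tau = c(20, 500), v = c(1, 10)) {
  rng <- list(D = D, f = f, tau = tau, v = v)
  for (nm in names(rng)) {
    x <- rng[[nm]]
    if (length(x) != 2 || x[1] >= x[2] || any(x < 0))
      stop("invalid range for ", nm)
  }
  structure(rng, class = "tissue_ranges")
}

#' Draw random tissue parameters
#'
#' Independent uniform draws per parameter from a [tissue_ranges()] object,
#' using the current RNG state (wrap in [withr::with_seed()] or set a seed
#' for reproducibility).
#'
#' @param ranges A [tissue_ranges()].
#' @param n Number of draws.
#' @return A data frame with columns `D`, `f`, `tau`, `v` (and `S0 = 1`).
#' @export
sample_tissue <- function(ranges, n = 1) {
  stopifnot(inherits(ranges, "tissue_ranges"), n >= 1)
  out <- lapply(ranges, function(r) stats::runif(n, r[1], r[2]))
  out <- as.data.frame(out)
  out$S0 <- 1
  out
}

#' Add Rician noise to a signal curve
#'
#' Per diffusion direction, the noisy magnitude signal is
#' `sqrt((S + e1)^2 + e2^2)` with Gaussian `e1, e2`; the returned signal is
#' the average over `n_directions` directions. With
#' `snr_scope = "effective"` (default) the per-direction noise SD is
#' `sqrt(n_directions) / snr_eff`, so that `snr_eff` is the SNR of the
#' direction-averaged b = 0 signal; `"per_direction"` uses `1 / snr_eff`
#' per direction instead.
#'
#' @param curve A normalized `signal_curve`.
#' @param snr_eff Signal-to-noise ratio at b = 0 (positive).
#' @param n_directions Number of averaged directions.
#' @param snr_scope `"effective"` or `"per_direction"`.
#' @return The curve with noisy signal values.
#' @export
add_rician <- function(curve, snr_eff, n_directions = 6,
                       snr_scope = c("effective", "per_direction")) {
  snr_scope <- match.arg(snr_scope)
  if (!is.finite(snr_eff) || snr_eff <= 0) stop("snr_eff must be positive")
  sigma <- if (snr_scope == "effective") sqrt(n_directions) / snr_eff
           else 1 / snr_eff
  n <- length(curve$signal)
  e1 <- matrix(stats::rnorm(n * n_directions, 0, sigma), n, n_directions)
  e2 <- matrix(stats::rnorm(n * n_directions, 0, sigma), n, n_directions)
  curve$signal <- rowMeans(sqrt((curve$signal + e1)^2 + e2^2))
  curve
}

#' Candidate-grid configuration
#'
#' The b-value grid is denser at low b (where most flow-related signal
#' change happens) and coarser at high b; the diffusion-time grid is finer
#' for flow-compensated shapes (diffusion time matters little for bipolar
#' encoding) and b is capped at `b_cap`.
#'
#' @param b Candidate b-values, s/mm^2.
#' @param T_bipolar,T_fc Candidate diffusion times per shape, ms.
#' @param b_cap Upper b-value cap, s/mm^2.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(b = c(0, 5, 10, 15, 20, 30, 40, 60, 80, 100, 125,
                              150, 200, 250, 300, 400, 500, 600, 700, 800),
                        T_bipolar = c(40, 70, 100),
                        T_fc = seq(40, 100, by = 10),
                        b_cap = 800) {
  stopifnot(all(b >= 0), all(diff(sort(b)) > 0), b_cap > 0)
  structure(list(b = sort(b), T_bipolar = T_bipolar, T_fc = T_fc,
                 b_cap = b_cap), class = "grid_config")
}

#' Feasible candidate acquisition points
#'
#' All (b, T, beta) combinations of a [grid_config()] that are realizable
#' under the hardware limits (`b <= max_b(beta, T)` and `b <= b_cap`).
#'
#' @param hw [hardware_limits()].
#' @param config [grid_config()].
#' @return A data frame of class `candidate_grid` with columns `b`, `T`,
#'   `beta`.
#' @export
candidate_grid <- function(hw = hardware_limits(), config = grid_config()) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  for (beta in 0:1) {
    Ts <- if (beta == 1) config$T_fc else config$T_bipolar
    Ts <- Ts[Ts >= hw$t_min & Ts <= hw$t_max]
    for (T in Ts) {
      bm <- min(max_b(beta, T, hw), config$b_cap)
      bs <- config$b[config$b <= bm]
      if (length(bs))
        rows[[length(rows) + 1L]] <- data.frame(b = bs, T = T, beta = beta)
    }
  }
  if (!length(rows)) stop("grid configuration excludes every candidate point")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("candidate_grid", "data.frame"))
}

#' @export
print.candidate_grid <- function(x, ...) {
  cat(sprintf("Candidate grid: %d feasible (b, T, beta) points (%d bipolar, %d FC)\n",
              nrow(x), sum(x$beta == 0), sum(x$beta == 1)))
  invisible(x)
}

#' Default five-point base scheme
#'
#' A minimal identifiable starting scheme (the model has five parameters):
#' b = 0 for both shapes at T = 100 ms, one high-b bipolar anchor, and
#' mid-b flow-compensated points at the shortest and longest diffusion
#' times. This is the package's own choice of starting set, not a canonical
#' one.
#'
#' @param hw [hardware_limits()].
#' @return An [acquisition_scheme()].
#' @export
base_scheme <- function(hw = hardware_limits()) {
  acquisition_scheme(b = c(0, 0, 600, 100, 150),
                     T = c(100, 100, 100, 40, 100),
                     beta = c(0, 1, 0, 1, 1),
                     label = "base5", hw = hw)
}

# append one candidate acquisition to a scheme (bumping n_repeats when the
# point is already present) without re-validating feasibility
add_point <- function(scheme, b, T, beta) {
  hit <- which(scheme$b == b & scheme$T == T & scheme$beta == beta)
  if (length(hit)) {
    scheme$n_repeats[hit[1]] <- scheme$n_repeats[hit[1]] + 1L
    return(scheme)
  }
  out <- rbind(as.data.frame(scheme),
               data.frame(b = b, T = T, beta = beta, n_repeats = 1L))
  structure(out, class = class(scheme), label = attr(scheme, "label"),
            n_directions = attr(scheme, "n_directions"))
}

# simulate -> noise -> fit -> per-parameter percent errors, for n_rep
# random tissues. Tissue draws happen first, then per-replicate noise, so
# two schemes with equal acquisition counts evaluated under the same seed
# see identical tissues and noise realizations.
simulate_errors <- function(scheme, truth, snr_eff, n_rep, bounds, norms,
                            seed, tbl, blood = blood_adc()) {
  pts <- scheme_points(scheme)
  n_dir <- attr(scheme, "n_directions") %||% 6
  fixed_truth <- inherits(truth, "tissue_params")
  run <- function() {
    tissues <- if (fixed_truth) {
      as.data.frame(as.list(unclass(truth)))[rep(1, n_rep), ]
    } else sample_tissue(truth, n_rep)
    tD <- tissues$D; tf <- tissues$f; ttau <- tissues$tau; tv <- tissues$v
    pre <- precompute_scheme(pts, blood, tbl)
    err <- matrix(NA_real_, n_rep, 4,
                  dimnames = list(NULL, c("D", "f", "tau", "v")))
    failed <- 0L
    cv0 <- signal_curve(data.frame(b = pts$b, T = pts$T, beta = pts$beta,
                                   signal = NA_real_), normalized = TRUE)
    for (i in seq_len(n_rep)) {
      cv <- cv0
      # truth curves use the full-resolution quantile table
      cv$signal <- model_signal_pre(c(1, tD[i], tf[i], ttau[i], tv[i]),
                                    pre, fit = FALSE)
      cv <- add_rician(cv, snr_eff, n_dir)
      cv <- normalize_curve(cv)
      init <- default_init(cv, bounds)
      ft <- fit_engine(cv$signal, pre, bounds, init)
      if (!ft$converged) failed <- failed + 1L
      tru <- c(D = tD[i], f = tf[i], tau = ttau[i], v = tv[i])
      nrm <- if (identical(norms, "truth")) "truth" else norms
      err[i, ] <- normalized_errors(tru, ft$par[c("D", "f", "tau", "v")], nrm)
    }
    list(err = err, failed = failed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Expected-error cost of an acquisition scheme
#'
#' Monte-Carlo estimate of the scheme's overall parameter error: for each
#' replicate a tissue is drawn from `ranges`, the forward signal is
#' simulated, Rician noise at `snr_eff` is added, the model is refit, and
#' the four normalized percent errors are aggregated as
#' `sqrt(mean(theta_err^2))`; the cost is the average over replicates
#' (`agg = "rms"`, default) or the average of `mean(theta_err^2)`
#' (`agg = "mean_square"`). Failed fits contribute their bound-clipped
#' estimates and are counted in the `n_failed` attribute.
#'
#' @param scheme An [acquisition_scheme()].
#' @param ranges A [tissue_ranges()] (or a fixed [tissue_params()]).
#' @param snr_eff Effective SNR at b = 0.
#' @param n_rep Number of Monte-Carlo replicates.
#' @param bounds Fit bounds (the broad optimizer set by default).
#' @param norms [error_norms()] used for Eq.-style percent errors.
#' @param seed RNG seed; two calls with the same seed and schemes of equal
#'   acquisition count see identical tissue and noise draws.
#' @param tbl Phase table.
#' @param agg Aggregation of the four squared errors per replicate.
#' @return Scalar cost (percent), with attribute `n_failed`.
#' @export
scheme_cost <- function(scheme, ranges = tissue_ranges(), snr_eff = 20,
                        n_rep = 500, bounds = fit_bounds("broad"),
                        norms = error_norms(), seed = NULL,
                        tbl = default_phase_table(),
                        agg = c("rms", "mean_square")) {
  agg <- match.arg(agg)
  assert_fittable(scheme)
  sim <- simulate_errors(scheme, ranges, snr_eff, n_rep, bounds, norms,
                         seed, tbl)
  per_rep <- rowMeans(sim$err^2)
  cost <- if (agg == "rms") mean(sqrt(per_rep)) else mean(per_rep)
  attr(cost, "n_failed") <- sim$failed
  cost
}

#' Greedy acquisition-scheme optimization
#'
#' Starting from an identifiable base scheme, repeatedly evaluates
#' [scheme_cost()] of the scheme extended by every candidate point — all
#' candidates sharing the same tissue and noise draws within a step — and
#' appends the argmin. Draws are refreshed between steps. Candidates may be
#' selected repeatedly (their repeat count then increases).
#'
#' @param base Base [acquisition_scheme()] (>= 5 acquisitions).
#' @param grid A [candidate_grid()].
#' @param n_add Number of acquisitions to add.
#' @inheritParams scheme_cost
#' @param seed Master seed; per-step seeds are derived from it.
#' @return An object of class `ivim_design`: the optimized scheme, the
#'   per-step trace (data frame with step, selected point, cost), and the
#'   inputs.
#' @export
greedy_optimize <- function(base, grid, n_add, ranges = tissue_ranges(),
                            snr_eff = 20, n_rep = 500,
                            bounds = fit_bounds("broad"),
                            norms = error_norms(), seed = 1,
                            tbl = default_phase_table(),
                            agg = c("rms", "mean_square")) {
  agg <- match.arg(agg)
  assert_fittable(base)
  stopifnot(nrow(grid) >= 1, n_add >= 1)
  step_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1L, n_add))
  scheme <- base
  trace <- vector("list", n_add)
  for (step in seq_len(n_add)) {
    costs <- vapply(seq_len(nrow(grid)), function(ci) {
      cand <- add_point(scheme, grid$b[ci], grid$T[ci], grid$beta[ci])
      as.numeric(scheme_cost(cand, ranges, snr_eff, n_rep, bounds, norms,
                             seed = step_seeds[step], tbl = tbl, agg = agg))
    }, numeric(1))
    best <- which.min(costs)
    scheme <- add_point(scheme, grid$b[best], grid$T[best], grid$beta[best])
    trace[[step]] <- data.frame(
      step = step, n_total = sum(base$n_repeats) + step,
      b = grid$b[best], T = grid$T[best], beta = grid$beta[best],
      cost = costs[best])
  }
  attr(scheme, "label") <- paste0(attr(base, "label"), "+opt", n_add)
  structure(list(scheme = scheme, trace = do.call(rbind, trace),
                 base = base, grid = grid, seed = seed,
                 snr_eff = snr_eff, n_rep = n_rep),
            class = "ivim_design")
}

#' @export
print.ivim_design <- function(x, ...) {
  cat(sprintf("Greedy acquisition design: %d points added to '%s' (n_rep = %d, SNR = %g)\n",
              nrow(x$trace), attr(x$base, "label"), x$n_rep, x$snr_eff))
  cat(sprintf("  cost: %.2f%% (N = %d) -> %.2f%% (N = %d)\n",
              x$trace$cost[1], x$trace$n_total[1],
              x$trace$cost[nrow(x$trace)], x$trace$n_total[nrow(x$trace)]))
  invisible(x)
}

#' @export
plot.ivim_design <- function(x, ...) {
  graphics::plot(x$trace$n_total, x$trace$cost, type = "b", pch = 16,
                 xlab = "total acquisitions N", ylab = "cost (%)", ...)
  N <- x$trace$n_total
  cfit <- stats::lm(x$trace$cost ~ I(1 / sqrt(N)))
  graphics::lines(N, stats::fitted(cfit), col = "red", lty = 2)
  invisible(x)
}

#' Evaluate a scheme's error percentiles
#'
#' Simulates `n_rep` noisy acquisitions and fits, and summarizes the
#' normalized percent error of each parameter by its 5/25/50/75/95
#' percentiles. With a fixed [tissue_params()] truth the errors are
#' normalized by the true values themselves; with [tissue_ranges()] they
#' are normalized by [error_norms()].
#'
#' @param scheme An [acquisition_scheme()].
#' @param truth A [tissue_params()] (fixed-truth mode) or [tissue_ranges()].
#' @param snr_eff Effective SNR at b = 0.
#' @param n_rep Replicates.
#' @param bounds Fit bounds (the tighter estimation set by default).
#' @param norms Normalization; default `"truth"` for fixed truth,
#'   [error_norms()] otherwise.
#' @param seed RNG seed.
#' @param tbl Phase table.
#' @return An object of class `scheme_eval`: percentile matrix (rows p5,
#'   p25, p50, p75, p95; columns D, f, tau, v), the raw error matrix, and
#'   run metadata.
#' @export
evaluate_scheme <- function(scheme, truth, snr_eff = 20, n_rep = 500,
                            bounds = fit_bounds(), norms = NULL,
                            seed = NULL, tbl = default_phase_table()) {
  if (is.null(norms))
    norms <- if (inherits(truth, "tissue_params")) "truth" else error_norms()
  assert_fittable(scheme)
  sim <- simulate_errors(scheme, truth, snr_eff, n_rep, bounds, norms,
                         seed, tbl)
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  pct <- apply(sim$err, 2, stats::quantile, probs = probs)
  rownames(pct) <- paste0("p", probs * 100)
  structure(list(percentiles = pct, errors = sim$err, n_rep = n_rep,
                 snr_eff = snr_eff, n_failed = sim$failed,
                 label = attr(scheme, "label")),
            class = "scheme_eval")
}

#' @export
print.scheme_eval <- function(x, ...) {
  cat(sprintf("Scheme '%s' error percentiles (%%, %d replicates, SNR %g)\n",
              x$label, x$n_rep, x$snr_eff))
  print(round(x$percentiles, 2))
  if (x$n_failed > 0)
    cat(sprintf("  %d fits reported non-convergence (bound-clipped)\n",
                x$n_failed))
  invisible(x)
}

#' Synthetic 50-point optimized-style scheme
#'
#' A hand-specified stand-in for an optimized 50-acquisition protocol,
#' mirroring the qualitative structure that greedy optimization produces:
#' flow-compensated measurements concentrated at long diffusion time
#' (T = 100 ms) with midrange b (60-150 s/mm^2, with repeats), bipolar
#' measurements preferring low b (0-30 s/mm^2), plus high-b bipolar anchors
#' for D. It is *synthetic* — not an optimizer output and not a published
#' protocol — and is intended for desk-scale evaluation runs.
#'
#' @param hw [hardware_limits()].
#' @return An [acquisition_scheme()] with 50 acquisitions.
#' @export
opt50_synthetic_scheme <- function(hw = hardware_limits()) {
  pts <- rbind(
    # base five
    data.frame(b = c(0, 0, 600, 100, 150), T = c(100, 100, 100, 40, 100),
               beta = c(0, 1, 0, 1, 1), n = 1L),
    # FC, long T, midrange b (repeated)
    data.frame(b = seq(60, 150, by = 10), T = 100, beta = 1, n = 2L),
    data.frame(b = c(30, 40, 50, 175, 200), T = 100, beta = 1, n = 1L),
    # FC at shorter diffusion times
    data.frame(b = c(60, 100, 150), T = 40, beta = 1, n = 1L),
    data.frame(b = c(80, 120), T = 70, beta = 1, n = 1L),
    # bipolar, low b
    data.frame(b = c(0, 0, 5, 10, 15, 20, 25, 30), T = 100, beta = 0, n = 1L),
    data.frame(b = c(10, 20, 30), T = 70, beta = 0, n = 1L),
    # bipolar high-b anchors for D
    data.frame(b = c(300, 450, 600, 750), T = 100, beta = 0, n = 1L))
  acquisition_scheme(b = pts$b, T = pts$T, beta = pts$beta,
                     n_repeats = pts$n, label = "opt50_synthetic", hw = hw)
}
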