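# Monte-Carlo model of the perfusion compartment: spins advect through a
# network of randomly oriented straight vessel segments at constant speed v,
# redrawing a uniformly random direction every time they enter a new segment.
# The traversal time of one segment is the characteristic time tau, so a
# spin crosses on average T/tau segments during the encoding. The phase
# accumulated under effective gradient G(t) is
#   phi = -v * sum_k cos(theta_k) * int_{segment k} q(t) dt,
# with q(t) = gamma int_0^t G, and the perfusion attenuation factor is the
# characteristic function F = E[cos(phi)] (the imaginary part vanishes by
# symmetry of the direction distribution).

#' Simulate spin phases for a gradient waveform
#'
#' Draws `n_spins` random vessel-segment trajectories (piecewise-constant
#' velocity of magnitude `v`, direction redrawn uniformly on the sphere at
#' segment boundaries, first boundary offset uniform in `[0, tau)`) and
#' accumulates the gradient-induced phase of each spin under the discretized
#' waveform.
#'
#' @param wf An [build_waveform()] result.
#' @param tau Characteristic segment traversal time, ms.
#' @param v Blood speed, mm/s.
#' @param n_spins Number of simulated spins.
#' @param seed RNG seed for reproducibility (optional).
#' @return An object of class `phase_ensemble`: accumulated phases (rad),
#'   `n_spins`, the segment ratio `T/tau`, and the seed used.
#' @examples
#' wf <- build_waveform(0, 70, 100)
#' ph <- sample_phases(wf, tau = 100, v = 2, n_spins = 1000, seed = 1)
#' mean(cos(ph$phases))
#' @export
sample_phases <- function(wf, tau, v, n_spins, seed = NULL) {
  stopifnot(inherits(wf, "ivim_waveform"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive (ms)")
  if (!is.finite(v) || v < 0) stop("v must be non-negative (mm/s)")
  if (n_spins < 1) stop("n_spins must be >= 1")
  t_s <- wf$time * 1e-3
  q <- waveform_integrals(wf$time, wf$G, wf$hw$gamma)$q    # rad/m
  # cumulative integral of q (rad*s/m), then interpolate at boundaries
  dt <- diff(t_s)
  Qc <- c(0, cumsum((q[-1] + q[-length(q)]) / 2 * dt))
  Qf <- stats::approxfun(t_s, Qc, rule = 2)
  tau_s <- tau * 1e-3
  v_si <- v * 1e-3
  T_s <- t_s[length(t_s)]
  run <- function() {
    u <- stats::runif(n_spins, 0, tau_s)
    K <- ceiling(T_s / tau_s) + 1L
    phases <- numeric(n_spins)
    for (k in 0:K) {
      starts <- if (k == 0L) rep(0, n_spins) else u + (k - 1L) * tau_s
      ends <- pmin(u + k * tau_s, T_s)
      live <- starts < T_s & ends > starts
      costh <- stats::runif(n_spins, -1, 1)
      if (!any(live)) break
      I <- numeric(n_spins)
      I[live] <- Qf(ends[live]) - Qf(pmin(starts[live], T_s))
      phases <- phases - v_si * costh * I
    }
    phases
  }
  phases <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(phases = phases, n_spins = n_spins,
                 ratio = wf$T / tau, seed = seed),
            class = "phase_ensemble")
}

#' @export
print.phase_ensemble <- function(x, ...) {
  cat(sprintf("Phase ensemble: %d spins, T/tau = %.3g, sd = %.3g rad\n",
              x$n_spins, x$ratio, stats::sd(x$phases)))
  invisible(x)
}

#' Perfusion attenuation factor by direct Monte-Carlo simulation
#'
#' Builds the requested waveform, simulates spin phases, and returns the
#' empirical mean of `cos(phase)`. The imaginary part `mean(sin(phase))`
#' vanishes by symmetry and is asserted to be within 3 Monte-Carlo standard
#' errors of zero before being discarded. `F` equals 1 exactly at `b = 0`
#' and may be negative in near-ballistic bipolar regimes (sinc lobes).
#'
#' @inheritParams build_waveform
#' @inheritParams sample_phases
#' @return The attenuation factor, a dimensionless scalar with |F| <= 1.
#' @examples
#' attenuation(b = 0, T = 70, beta = 0, tau = 100, v = 3, n_spins = 100)
#' @seealso [phase_table()] for the cached fast path used inside fits.
#' @export
attenuation <- function(b, T, beta, tau, v, n_spins = 1e4, seed = NULL,
                        hw = hardware_limits(), dt = 0.01) {
  wf <- build_waveform(beta, T, b, hw, dt)
  ph <- sample_phases(wf, tau, v, n_spins, seed)
  im <- mean(sin(ph$phases))
  im_se <- stats::sd(sin(ph$phases)) / sqrt(n_spins)
  if (is.finite(im_se) && im_se > 0 && abs(im) > 3 * im_se + 1e-12)
    warning(sprintf("imaginary part of F (%.3g) exceeds 3 MC standard errors",
                    im))
  mean(cos(ph$phases))
}

# --- cached phase tables -----------------------------------------------

# Normalized phases for the ideal rectangular-lobe shape at unit amplitude,
# unit duration and unit gamma: X = sum_k cos(theta_k) * dQhat_k. The
# physical phase is v * sqrt(b_SI * T_SI / kappa_beta) * X, so one table per
# (beta, T/tau) serves every (b, v).
sample_phases_norm <- function(beta, ratio, n_spins) {
  tau_n <- 1 / ratio
  u <- stats::runif(n_spins, 0, tau_n)
  K <- ceiling(ratio) + 1L
  X <- numeric(n_spins)
  Q_end <- numeric(n_spins)          # Qhat at the current segment start
  for (k in 0:K) {
    starts <- if (k == 0L) numeric(n_spins) else u + (k - 1L) * tau_n
    ends <- pmin(u + k * tau_n, 1)
    live <- starts < 1
    costh <- stats::runif(n_spins, -1, 1)
    Q_start <- Q_end
    Q_end[live] <- Qhat_norm(ends[live], beta)
    X[live] <- X[live] - costh[live] * (Q_end[live] - Q_start[live])
    if (all(ends >= 1)) break
  }
  X
}

#' Precompute normalized phase-distribution tables
#'
#' For each gradient shape and each node of a logarithmic grid of the
#' segment ratio `T/tau`, simulates the normalized phase distribution once
#' and stores it as bin means of the sorted sample (a quantile
#' representation of the distribution). [attenuation_table()] then evaluates
#' the attenuation factor for arbitrary `(b, T, tau, v)` by cubic
#' (Catmull-Rom) interpolation of the quantile functions across `log(T/tau)`
#' followed by a cosine quadrature. The build uses a fixed internal seed so
#' the table is a deterministic object.
#'
#' @param n_spins Spins per grid node (default 102400 = 512 bins x 200).
#' @param n_nodes Number of `T/tau` grid nodes (default 64).
#' @param n_bins Quantile bins stored per node (default 512).
#' @param n_fit Coarser bin count used on the fast path inside fits
#'   (default 64).
#' @param r_range Range of `T/tau` covered (default `c(0.01, 100)`).
#' @return An object of class `phase_table`.
#' @export
phase_table <- function(n_spins = 102400, n_nodes = 64, n_bins = 512,
                        n_fit = 64, r_range = c(1e-2, 1e2)) {
  stopifnot(n_spins %% n_bins == 0, n_bins %% n_fit == 0)
  logr <- seq(log(r_range[1]), log(r_range[2]), length.out = n_nodes)
  r <- exp(logr)
  per_bin <- n_spins / n_bins
  build_beta <- function(beta) {
    q <- matrix(0, n_bins, n_nodes)
    for (j in seq_len(n_nodes)) {
      X <- sort(sample_phases_norm(beta, r[j], n_spins))
      q[, j] <- colMeans(matrix(X, per_bin, n_bins))
    }
    q
  }
  tbl <- withr::with_seed(20190930L, list(build_beta(0), build_beta(1)))
  agg <- n_bins / n_fit
  fit_tbl <- lapply(tbl, function(q)
    apply(q, 2, function(col) colMeans(matrix(col, agg, n_fit))))
  structure(list(r = r, logr = logr, h = logr[2] - logr[1],
                 quantiles = tbl, quantiles_fit = fit_tbl,
                 n_spins = n_spins, n_bins = n_bins, n_fit = n_fit),
            class = "phase_table")
}

#' @export
print.phase_table <- function(x, ...) {
  cat(sprintf(
    "Phase table: %d T/tau nodes in [%.3g, %.3g], %d bins (%d spins/node)\n",
    length(x$r), min(x$r), max(x$r), x$n_bins, x$n_spins))
  invisible(x)
}

# Interpolate the stored quantile vectors at segment ratio `ratio` for one
# shape. Catmull-Rom across log(T/tau); clamped at the grid edges.
interp_quantiles <- function(tbl, beta, ratio, fit = FALSE) {
  q <- .subset2(if (fit) tbl$quantiles_fit else tbl$quantiles, beta + 1L)
  logr <- tbl$logr
  n <- length(logr)
  lr <- log(ratio)
  if (lr < logr[1L]) lr <- logr[1L] else if (lr > logr[n]) lr <- logr[n]
  j <- floor((lr - logr[1L]) / tbl$h) + 1L
  if (j >= n) j <- n - 1L
  u <- (lr - logr[j]) / tbl$h
  p0 <- q[, if (j > 1L) j - 1L else 1L]; p1 <- q[, j]
  p2 <- q[, j + 1L]; p3 <- q[, if (j + 2L < n) j + 2L else n]
  u2 <- u * u; u3 <- u2 * u
  0.5 * ((2 * p1) + (p2 - p0) * u + (2 * p0 - 5 * p1 + 4 * p2 - p3) * u2 +
         (3 * p1 - p0 - 3 * p2 + p3) * u3)
}

#' Attenuation factor from a cached phase table
#'
#' Fast, deterministic evaluation of the perfusion attenuation factor
#' `F(b, T, beta, tau, v)` from a precomputed [phase_table()]. Vectorized
#' over its numeric arguments (recycled to a common length).
#'
#' @param tbl A [phase_table()]; defaults to the lazily built package table.
#' @param b b-value(s), s/mm^2.
#' @param T Diffusion time(s), ms.
#' @param beta Gradient shape(s), 0 or 1.
#' @param tau Characteristic time(s), ms.
#' @param v Blood speed(s), mm/s.
#' @param fit Use the coarser fast-path quantile resolution.
#' @return Vector of attenuation factors.
#' @export
attenuation_table <- function(b, T, beta, tau, v, tbl = default_phase_table(),
                              fit = FALSE) {
  n <- max(length(b), length(T), length(beta), length(tau), length(v))
  b <- rep_len(b, n); T <- rep_len(T, n); beta <- rep_len(beta, n)
  tau <- rep_len(tau, n); v <- rep_len(v, n)
  check_beta(beta)
  # phase scale: v_SI * sqrt(b_SI * T_SI / kappa)
  s <- (v * 1e-3) * sqrt(b * 1e6 * T * 1e-3 / kappa_shape(beta))
  out <- numeric(n)
  key <- paste(beta, T / tau)
  for (g in split(seq_len(n), key)) {
    Xq <- interp_quantiles(tbl, beta[g[1]], T[g[1]] / tau[g[1]], fit = fit)
    out[g] <- colMeans(cos(outer(Xq, s[g])))
  }
  out
}

.fcivim_env <- new.env(parent = emptyenv())

#' Shared package phase table
#'
#' Returns the package-wide cached [phase_table()], building it on first use
#' (a few seconds of Monte-Carlo simulation with a fixed internal seed).
#' @return A `phase_table`.
#' @export
default_phase_table <- function() {
  if (is.null(.fcivim_env$table)) .fcivim_env$table <- phase_table()
  .fcivim_env$table
}
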