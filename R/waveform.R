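# Diffusion-encoding gradient waveforms.
#
# Both encodings are modelled as trapezoidal lobes of the *effective*
# gradient (the sign flip of the refocusing pulse folded in), filling the
# diffusion time T:
#   bipolar (beta = 0):          +g [0, T/2],  -g [T/2, T]
#   flow-compensated (beta = 1): +g [0, T/4], -g [T/4, T/2],
#                                -g [T/2, 3T/4], +g [3T/4, T]
# Each lobe ramps at the slew limit. Both shapes have zero net area (the
# spin-echo condition); the FC shape is additionally time-symmetric, which
# nulls the first gradient moment exactly, making it insensitive to
# constant-velocity motion.

# Ideal (zero-ramp) normalized shape constants: for unit amplitude and unit
# duration, kappa = integral of qhat(t)^2 with qhat(t) = int_0^t ghat.
# b = gamma^2 g^2 T^3 kappa. FC lobes are 4x less b-efficient.
KAPPA_BIPOLAR <- 1 / 12
KAPPA_FC <- 1 / 48

kappa_shape <- function(beta) ifelse(beta == 1, KAPPA_FC, KAPPA_BIPOLAR)

# Normalized dephasing qhat(t) and its running integral Qhat(t) on [0,1]
# for the ideal rectangular-lobe shapes (used by the cached phase tables).
qhat_norm <- function(t, beta) {
  if (beta == 0) ifelse(t < 0.5, t, 1 - t)
  else ifelse(t < 0.25, t,
       ifelse(t < 0.5, 0.5 - t,
       ifelse(t < 0.75, 0.5 - t, t - 1)))
}

Qhat_norm <- function(t, beta) {
  t <- pmin(pmax(t, 0), 1)
  out <- numeric(length(t))
  if (beta == 0) {
    a <- t < 0.5
    out[a] <- t[a]^2 / 2
    out[!a] <- t[!a] - t[!a]^2 / 2 - 0.25
  } else {
    i1 <- t < 0.25
    i2 <- !i1 & t < 0.5
    i3 <- t >= 0.5 & t < 0.75
    i4 <- t >= 0.75
    out[i1] <- t[i1]^2 / 2
    out[i2] <- t[i2] / 2 - t[i2]^2 / 2 - 1 / 16
    out[i3] <- 1 / 16 - (t[i3] - 0.5)^2 / 2
    out[i4] <- t[i4]^2 / 2 - t[i4] + 0.5
  }
  out
}

# Trapezoidal lobe on grid `t` (ms): amplitude `a` (signed, mT/m) over
# [t0, t1] with ramps of duration r at both ends.
trap_lobe <- function(t, t0, t1, a, r) {
  inside <- t >= t0 & t <= t1
  frac <- pmin(1, (t - t0) / r, (t1 - t) / r)
  ifelse(inside, a * pmax(frac, 0), 0)
}

waveform_samples <- function(beta, T, g, hw, dt) {
  r <- g / hw$slew_max                    # ramp time, ms
  n_lobes <- if (beta == 1) 4L else 2L
  if (T / n_lobes < 2 * r)
    stop("lobe too short for slew-limited ramps at this amplitude")
  t <- seq(0, T, by = dt)
  if (beta == 0) {
    G <- trap_lobe(t, 0, T / 2, g, r) + trap_lobe(t, T / 2, T, -g, r)
  } else {
    G <- trap_lobe(t, 0,       T / 4,     g, r) +
         trap_lobe(t, T / 4,   T / 2,    -g, r) +
         trap_lobe(t, T / 2,   3 * T / 4, -g, r) +
         trap_lobe(t, 3 * T / 4, T,       g, r)
  }
  list(time = t, G = G)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# b-value (s/mm^2) and first moment (rad*s/m, as -int q dt) recomputed from
# discretized samples; time in ms, G in mT/m.
waveform_integrals <- function(time, G, gamma) {
  t_s <- time * 1e-3
  G_T <- G * 1e-3                          # T/m
  dt <- diff(t_s)
  # q(t) = gamma * int G dt'  [rad/m], trapezoidal cumulative
  q <- gamma * c(0, cumsum((G_T[-1] + G_T[-length(G_T)]) / 2 * dt))
  b_si <- trapz(t_s, q^2)                  # s/m^2
  m1 <- -trapz(t_s, q)                     # rad*s/m
  list(q = q, b = b_si * 1e-6, m1 = m1)
}

#' Build a diffusion-encoding gradient waveform
#'
#' Constructs a slew-limited trapezoidal bipolar (`beta = 0`) or
#' flow-compensated (`beta = 1`) effective gradient waveform of duration `T`
#' whose amplitude is solved so that the b-value recomputed from the
#' discretized samples hits `b` to within 0.1\%.
#'
#' @param beta Gradient shape: 0 = bipolar, 1 = flow-compensated.
#' @param T Diffusion time, ms.
#' @param b Target b-value, s/mm^2.
#' @param hw [hardware_limits()].
#' @param dt Sampling interval, ms (default 0.01, i.e. 10 microseconds).
#' @return An object of class `ivim_waveform`: sampled time (ms) and
#'   amplitude (mT/m), the recomputed b-value (s/mm^2), the first gradient
#'   moment `m1` (rad s/m; zero for flow-compensated shapes), and the solved
#'   plateau amplitude (mT/m).
#' @examples
#' wf <- build_waveform(beta = 0, T = 70, b = 200)
#' wf$b
#' @seealso [max_b()] for the largest achievable b-value.
#' @export
build_waveform <- function(beta, T, b, hw = hardware_limits(), dt = 0.01) {
  check_beta(beta)
  check_T(T, hw)
  if (!is.finite(b) || b < 0) stop("target b must be a non-negative number")
  bmax <- max_b(beta, T, hw, dt)
  if (b > bmax)
    stop(sprintf(
      "b = %g s/mm^2 not achievable: max_b(beta = %d, T = %g) = %.1f s/mm^2",
      b, beta, T, bmax))
  if (b == 0) {
    g <- 0
    sm <- list(time = seq(0, T, by = dt), G = numeric(length(seq(0, T, by = dt))))
  } else {
    # b is monotone increasing in plateau amplitude; solve for it
    f <- function(g) {
      sm <- waveform_samples(beta, T, g, hw, dt)
      waveform_integrals(sm$time, sm$G, hw$gamma)$b - b
    }
    g <- stats::uniroot(f, c(1e-6, hw$g_max), tol = 1e-10)$root
    sm <- waveform_samples(beta, T, g, hw, dt)
  }
  ints <- waveform_integrals(sm$time, sm$G, hw$gamma)
  structure(list(beta = beta, T = T, time = sm$time, G = sm$G,
                 b = ints$b, m1 = ints$m1, g_amp = g, hw = hw, dt = dt),
            class = "ivim_waveform")
}

#' Largest achievable b-value for a gradient shape and diffusion time
#'
#' The b-value of the waveform played at the gradient amplitude limit.
#' Flow-compensated shapes are a factor ~4 less b-efficient than bipolar
#' ones at equal amplitude and duration.
#'
#' @inheritParams build_waveform
#' @return Maximum b-value, s/mm^2.
#' @examples
#' max_b(0, 100) > max_b(0, 40)
#' @export
max_b <- function(beta, T, hw = hardware_limits(), dt = 0.01) {
  check_beta(beta)
  check_T(T, hw)
  sm <- waveform_samples(beta, T, hw$g_max, hw, dt)
  waveform_integrals(sm$time, sm$G, hw$gamma)$b
}

#' @export
print.ivim_waveform <- function(x, ...) {
  cat(sprintf("%s gradient waveform\n",
              if (x$beta == 1) "Flow-compensated" else "Bipolar"))
  cat(sprintf("  T = %g ms, b = %.2f s/mm^2, amplitude = %.3f mT/m\n",
              x$T, x$b, x$g_amp))
  cat(sprintf("  first moment m1 = %.3e rad s/m, %d samples (dt = %g ms)\n",
              x$m1, length(x$time), x$dt))
  invisible(x)
}

#' @export
plot.ivim_waveform <- function(x, ...) {
  graphics::plot(x$time, x$G, type = "l", xlab = "time (ms)",
                 ylab = "effective gradient (mT/m)", ...)
  graphics::abline(h = 0, col = "grey70")
  invisible(x)
}

#' Write a waveform to a two-column CSV
#'
#' Columns `time_ms` and `amplitude_mT_m`.
#'
#' @param wf An `ivim_waveform`.
#' @param path Output file path.
#' @export
write_waveform <- function(wf, path) {
  stopifnot(inherits(wf, "ivim_waveform"))
  utils::write.csv(data.frame(time_ms = wf$time, amplitude_mT_m = wf$G),
                   path, row.names = FALSE)
  invisible(path)
}
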