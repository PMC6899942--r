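# Two-compartment FC-IVIM forward signal:
#   S(b,T,beta) = S0 * [ (1-f) e^{-b D}
#                        + f F(b,T,beta,tau,v) e^{-b Db(beta)} ],
# where F is the perfusion attenuation factor of the phase model and
# Db(beta) is the apparent diffusion coefficient of blood for the given
# gradient shape.

#' Tissue parameter set
#'
#' @param D Tissue diffusivity, mm^2/s (e.g. 1.5e-3).
#' @param f Perfusion (signal) fraction, as a fraction in `[0, 1]`.
#' @param tau Characteristic vessel-segment traversal time, ms.
#' @param v Blood speed, mm/s.
#' @param S0 Unweighted signal (arbitrary units).
#' @return An object of class `tissue_params` (a named numeric vector).
#' @examples
#' liver_literature <- tissue_params(D = 1.12e-3, f = 0.347, tau = 144, v = 4.60)
#' @export
tissue_params <- function(D, f, tau, v, S0 = 1) {
  stopifnot(D >= 0, f >= 0, f <= 1, tau >= 0, v >= 0, S0 >= 0)
  structure(c(D = D, f = f, tau = tau, v = v, S0 = S0),
            class = "tissue_params")
}

#' Apparent diffusion coefficients of flowing blood
#'
#' Shape-specific blood ADCs entering the perfusion compartment, mm^2/s.
#' Literature values are commonly printed in units that would annihilate
#' the perfusion compartment at any appreciable b; the defaults here are
#' 1.30e-3 (bipolar) and 1.54e-3 (flow-compensated) mm^2/s.
#'
#' @param bipolar,fc Blood ADC for each gradient shape, mm^2/s.
#' @return An object of class `blood_adc`.
#' @export
blood_adc <- function(bipolar = 1.30e-3, fc = 1.54e-3) {
  stopifnot(bipolar > 0, fc > 0)
  if (fc < bipolar) stop("blood ADC for FC gradients should be >= bipolar")
  structure(c(bipolar = bipolar, fc = fc), class = "blood_adc")
}

#' Acquisition scheme
#'
#' An ordered table of (b, T, beta) measurement settings with per-point
#' repeat counts. A fittable scheme needs at least 5 points (the model has
#' 5 free parameters) including at least one b = 0 point for normalization.
#'
#' @param b b-values, s/mm^2.
#' @param T Diffusion times, ms (recycled).
#' @param beta Gradient shapes, 0 or 1 (recycled).
#' @param n_repeats Identical repeats per point (recycled, default 1).
#' @param label Optional scheme label.
#' @param n_directions Diffusion directions averaged per acquisition
#'   (default 6).
#' @param hw [hardware_limits()] used for feasibility validation.
#' @param validate Check feasibility (b <= max_b, T in range). Set FALSE
#'   only for deliberately unconstrained toy schemes.
#' @return A data frame of class `acquisition_scheme` with columns
#'   `b`, `T`, `beta`, `n_repeats`.
#' @examples
#' sc <- acquisition_scheme(b = c(0, 10, 50, 200, 500), T = 100,
#'                          beta = c(0, 1, 1, 0, 0))
#' @export
acquisition_scheme <- function(b, T = 100, beta = 0, n_repeats = 1,
                               label = "scheme", n_directions = 6,
                               hw = hardware_limits(), validate = TRUE) {
  n <- length(b)
  df <- data.frame(b = b, T = rep_len(T, n), beta = rep_len(beta, n),
                   n_repeats = rep_len(as.integer(n_repeats), n))
  check_beta(df$beta)
  if (any(df$b < 0)) stop("b-values must be non-negative")
  if (any(df$n_repeats < 1)) stop("n_repeats must be >= 1")
  if (validate) {
    bad <- integer(0)
    for (i in seq_len(n)) {
      ok <- df$T[i] >= hw$t_min && df$T[i] <= hw$t_max &&
        df$b[i] <= max_b(df$beta[i], min(max(df$T[i], hw$t_min), hw$t_max), hw)
      if (!ok) bad <- c(bad, i)
    }
    if (length(bad))
      stop("infeasible acquisition points (T out of range or b > max_b) ",
           "in rows: ", paste(bad, collapse = ", "))
  }
  structure(df, class = c("acquisition_scheme", "data.frame"),
            label = label, n_directions = n_directions)
}

scheme_points <- function(scheme) {
  # expand n_repeats into individual acquisitions
  idx <- rep(seq_len(nrow(scheme)), scheme$n_repeats)
  scheme[idx, c("b", "T", "beta"), drop = FALSE]
}

assert_fittable <- function(scheme) {
  pts <- scheme_points(scheme)
  if (nrow(pts) < 5)
    stop("at least five acquisitions are required to fit the 5-parameter model")
  if (!any(pts$b == 0))
    stop("scheme needs at least one b = 0 acquisition for normalization")
  invisible(scheme)
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme '%s': %d points (%d acquisitions), %d directions\n",
              attr(x, "label"), nrow(x), sum(x$n_repeats),
              attr(x, "n_directions")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Evaluate the FC-IVIM forward signal
#'
#' Computes the model signal for every acquisition of a scheme (repeats
#' expanded) at the given tissue parameters.
#'
#' @param scheme An [acquisition_scheme()].
#' @param tissue A [tissue_params()].
#' @param blood A [blood_adc()].
#' @param method `"table"` (default; deterministic, cached phase table) or
#'   `"mc"` (direct Monte-Carlo attenuation per point).
#' @param tbl Phase table for `method = "table"`.
#' @param n_spins,seed Monte-Carlo controls for `method = "mc"`.
#' @return A `signal_curve`: data frame with the expanded acquisition
#'   settings and a `signal` column; attribute `normalized` is `FALSE`.
#' @examples
#' sc <- acquisition_scheme(b = c(0, 10, 50, 200, 500), T = 100,
#'                          beta = c(0, 1, 1, 0, 0))
#' forward_signal(sc, tissue_params(1.5e-3, 0.2, 150, 4))
#' @export
forward_signal <- function(scheme, tissue, blood = blood_adc(),
                           method = c("table", "mc"),
                           tbl = default_phase_table(),
                           n_spins = 1e4, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "acquisition_scheme"),
            inherits(tissue, "tissue_params"))
  pts <- scheme_points(scheme)
  Ff <- if (method == "table") {
    attenuation_table(pts$b, pts$T, pts$beta, tissue[["tau"]], tissue[["v"]],
                      tbl = tbl)
  } else {
    vapply(seq_len(nrow(pts)), function(i)
      attenuation(pts$b[i], pts$T[i], pts$beta[i], tissue[["tau"]],
                  tissue[["v"]], n_spins = n_spins,
                  seed = if (is.null(seed)) NULL else seed + i),
      numeric(1))
  }
  db <- ifelse(pts$beta == 1, blood[["fc"]], blood[["bipolar"]])
  S <- tissue[["S0"]] * ((1 - tissue[["f"]]) * exp(-pts$b * tissue[["D"]]) +
                         tissue[["f"]] * Ff * exp(-pts$b * db))
  out <- data.frame(b = pts$b, T = pts$T, beta = pts$beta, signal = S)
  structure(out, class = c("signal_curve", "data.frame"),
            normalized = FALSE, n_directions = attr(scheme, "n_directions"),
            label = attr(scheme, "label"))
}

signal_curve <- function(df, normalized = FALSE, n_directions = 6,
                         label = "curve") {
  stopifnot(all(c("b", "T", "beta", "signal") %in% names(df)))
  structure(as.data.frame(df)[c("b", "T", "beta", "signal")],
            class = c("signal_curve", "data.frame"),
            normalized = normalized, n_directions = n_directions,
            label = label)
}

#' @export
print.signal_curve <- function(x, ...) {
  cat(sprintf("Signal curve '%s' (%d acquisitions, %snormalized)\n",
              attr(x, "label"), nrow(x),
              if (isTRUE(attr(x, "normalized"))) "" else "not "))
  print.data.frame(x, ...)
  invisible(x)
}
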