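# Self-contained in-silico repeatability study: multi-subject,
# multi-session ROI-median signal-decay curves with linear drift and Rician
# noise, so the whole drift-correction -> fit -> wCV/ICC pipeline runs
# without any external data.

default_organ_table <- function() {
  # per-organ population mean +/- SD of the tissue parameters
  data.frame(
    organ = c("liver", "spleen", "kidney"),
    D_mean = c(1.61e-3, 0.84e-3, 2.30e-3),
    D_sd = c(0.16e-3, 0.07e-3, 0.16e-3),
    f_mean = c(0.450, 0.093, 0.194),
    f_sd = c(0.047, 0.027, 0.019),
    tau_mean = c(171, 147, 71),
    tau_sd = c(19, 54, 22),
    v_mean = c(8.4, 5.9, 10.8),
    v_sd = c(0.6, 2.8, 1.5))
}

#' Configuration of the synthetic repeatability study
#'
#' Describes the simulated cohort: number of subjects, per-organ population
#' means and SDs of the tissue parameters, a session layout of two
#' intrasession measurements plus one intersession measurement, a
#' between-occasion biological coefficient of variation, per-ROI linear
#' signal drift, and the acquisition scheme and SNR.
#'
#' @param n_subjects Number of subjects (default 7).
#' @param organs Data frame like `fcivim:::default_organ_table()` with
#'   columns `organ`, and `<param>_mean` / `<param>_sd` for D, f, tau, v.
#' @param occasions Measurement occasion labels; the first two form the
#'   intrasession pair, the first and last the intersession pair.
#' @param between_cv Between-occasion biological CV of each parameter, \%.
#' @param drift_slope_max Largest absolute relative drift slope, per second;
#'   slopes are drawn uniformly in `[-drift_slope_max, drift_slope_max]`.
#' @param drift_frac Fraction of ROI series given a nonzero drift slope.
#' @param snr_eff Effective SNR at b = 0.
#' @param scheme Acquisition scheme (default [opt50_synthetic_scheme()]).
#' @param dt_acq Spacing between consecutive acquisitions, s.
#' @param S0 Unweighted ROI-median signal scale, arbitrary units.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 7, organs = default_organ_table(),
                         occasions = c("ses1a", "ses1b", "ses2"),
                         between_cv = 5, drift_slope_max = 2e-4,
                         drift_frac = 0.5, snr_eff = 20,
                         scheme = opt50_synthetic_scheme(),
                         dt_acq = 20, S0 = 100) {
  stopifnot(n_subjects >= 2, length(occasions) >= 2, between_cv >= 0,
            drift_slope_max >= 0, drift_frac >= 0, drift_frac <= 1,
            snr_eff > 0, dt_acq > 0, S0 > 0)
  need <- c("organ", paste0(rep(c("D", "f", "tau", "v"), each = 2),
                            c("_mean", "_sd")))
  if (!all(need %in% names(organs))) stop("organs table is missing columns")
  if (any(organs[grep("_sd$", names(organs))] < 0))
    stop("organ parameter SDs must be non-negative")
  structure(list(n_subjects = n_subjects, organs = organs,
                 occasions = occasions, between_cv = between_cv,
                 drift_slope_max = drift_slope_max, drift_frac = drift_frac,
                 snr_eff = snr_eff, scheme = scheme, dt_acq = dt_acq,
                 S0 = S0),
            class = "study_config")
}

# truncated-normal draw by rejection, bounded by the organ fit constraints
# (slightly inset) so generated truths stay identifiable
rtrunc <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) && tries < 100L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    tries <- tries + 1L
  }
  if (length(bad)) out[bad] <- pmin(pmax(out[bad], lo), hi)
  out
}

organ_truth_bounds <- function(organ) {
  b <- organ_bounds(if (organ %in% c("liver", "spleen")) organ else "kidney")
  lapply(b[c("D", "f", "tau", "v")], function(x)
    c(x[1] + 0.02 * (x[2] - x[1]), x[2] - 0.02 * (x[2] - x[1])))
}

#' Generate a synthetic multi-subject repeatability study
#'
#' Per subject and organ, draws true tissue parameters from truncated
#' normal distributions at the configured population means and SDs; per
#' measurement occasion, jitters them multiplicatively by the
#' between-occasion CV; then synthesizes the ROI-median signal-decay curve
#' with the forward model, applies a linear signal drift `(1 + slope * t)`
#' to a random subset of series, and adds Rician noise. Fully reproducible
#' under `seed`.
#'
#' @param config A [study_config()].
#' @param seed RNG seed.
#' @param tbl Phase table.
#' @return An object of class `ivim_study`: `truth` (data frame of
#'   per-occasion true parameters, including the applied drift slope) and
#'   `series` (long data frame of signals with subject, organ, occasion,
#'   time, b, T, beta).
#' @export
generate_study <- function(config = study_config(), seed = 1,
                           tbl = default_phase_table()) {
  stopifnot(inherits(config, "study_config"))
  scheme <- config$scheme
  pts <- scheme_points(scheme)
  n_dir <- attr(scheme, "n_directions") %||% 6
  time <- seq(0, by = config$dt_acq, length.out = nrow(pts))
  run <- function() {
    truth <- list(); series <- list()
    for (si in seq_len(config$n_subjects)) {
      for (oi in seq_len(nrow(config$organs))) {
        org <- config$organs[oi, ]
        tb <- organ_truth_bounds(org$organ)
        subj <- c(D = rtrunc(1, org$D_mean, org$D_sd, tb$D[1], tb$D[2]),
                  f = rtrunc(1, org$f_mean, org$f_sd, tb$f[1], tb$f[2]),
                  tau = rtrunc(1, org$tau_mean, org$tau_sd, tb$tau[1],
                               tb$tau[2]),
                  v = rtrunc(1, org$v_mean, org$v_sd, tb$v[1], tb$v[2]))
        for (occ in config$occasions) {
          jit <- stats::rnorm(4, 1, config$between_cv / 100)
          par <- pmin(pmax(subj * jit,
                           vapply(tb, `[`, numeric(1), 1L)),
                      vapply(tb, `[`, numeric(1), 2L))
          drift <- if (stats::runif(1) < config$drift_frac)
            stats::runif(1, -config$drift_slope_max, config$drift_slope_max)
          else 0
          tis <- tissue_params(par[["D"]], par[["f"]], par[["tau"]],
                               par[["v"]], S0 = 1)
          sig <- forward_signal(scheme, tis, tbl = tbl)
          sig$signal <- sig$signal * (1 + drift * time)
          sig <- add_rician(sig, config$snr_eff, n_dir)
          truth[[length(truth) + 1L]] <- data.frame(
            subject = si, organ = org$organ, occasion = occ,
            D = par[["D"]], f = par[["f"]], tau = par[["tau"]],
            v = par[["v"]], drift_slope = drift)
          series[[length(series) + 1L]] <- data.frame(
            subject = si, organ = org$organ, occasion = occ,
            time = time, b = sig$b, T = sig$T, beta = sig$beta,
            signal = config$S0 * sig$signal)
        }
      }
    }
    list(truth = do.call(rbind, truth), series = do.call(rbind, series))
  }
  out <- withr::with_seed(seed, run())
  structure(list(config = config, truth = out$truth, series = out$series,
                 seed = seed),
            class = "ivim_study")
}

#' @export
print.ivim_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic repeatability study: %d subjects x %d organs x %d occasions (seed %d)\n",
    x$config$n_subjects, nrow(x$config$organs),
    length(x$config$occasions), x$seed))
  invisible(x)
}

#' Fit all ROI series of a study
#'
#' Runs the full estimation pipeline per subject x organ x occasion:
#' drift detection/correction on the b = 0 signal, then the constrained
#' FC-IVIM fit under the organ-specific bounds.
#'
#' @param study An [generate_study()] result (or a long data frame shaped
#'   like its `series` element).
#' @param drift_alpha Significance level for the drift slope test.
#' @param tbl Phase table.
#' @return Data frame of class `repeatability_table` with one row per
#'   series: subject, organ, occasion, the four parameter estimates,
#'   `converged` and `drift_corrected`.
#' @export
fit_study <- function(study, drift_alpha = 0.05,
                      tbl = default_phase_table()) {
  series <- if (inherits(study, "ivim_study")) study$series else study
  stopifnot(all(c("subject", "organ", "occasion", "time", "b", "T", "beta",
                  "signal") %in% names(series)))
  keys <- unique(series[c("subject", "organ", "occasion")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sel <- series$subject == keys$subject[i] &
      series$organ == keys$organ[i] & series$occasion == keys$occasion[i]
    ser <- series[sel, ]
    dc <- drift_correct(ser, alpha = drift_alpha)
    organ <- as.character(keys$organ[i])
    bounds <- organ_bounds(if (organ %in% c("liver", "spleen")) organ
                           else "kidney")
    # a few spread-out (tau, v) restarts guard against the local minima of
    # the flow-parameter valley on individual ROI curves
    fit <- fcivim(dc$series, bounds = bounds, tbl = tbl,
                  extra_starts = list(c(tau = 100, v = 9),
                                      c(tau = 350, v = 6),
                                      c(tau = 60, v = 2)))
    p <- coef(fit)
    rows[[i]] <- data.frame(
      subject = keys$subject[i], organ = organ,
      occasion = keys$occasion[i], D = p[["D"]], f = p[["f"]],
      tau = p[["tau"]], v = p[["v"]], S0 = p[["S0"]],
      converged = fit$converged, drift_corrected = dc$corrected)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("repeatability_table", "data.frame")
  out
}

#' Repeatability summary of a fitted study
#'
#' Per organ and parameter: intrasession wCV (first two occasions),
#' intersession wCV (first and last occasion), and the absolute-agreement
#' average-measures ICC over all occasions.
#'
#' @param table A [fit_study()] result.
#' @param params Parameter columns to summarize.
#' @return Data frame with columns organ, parameter, wcv_intra, wcv_inter,
#'   icc, reliability.
#' @export
repeatability_summary <- function(table, params = c("D", "f", "tau", "v")) {
  stopifnot(all(c("subject", "organ", "occasion", params) %in% names(table)))
  occ <- unique(as.character(table$occasion))
  if (length(occ) < 2) stop("need at least two occasions")
  intra <- occ[1:2]
  inter <- c(occ[1], occ[length(occ)])
  rows <- list()
  for (org in unique(as.character(table$organ))) {
    sub <- table[table$organ == org, ]
    for (p in params) {
      ti <- sub[sub$occasion %in% intra, ]
      te <- sub[sub$occasion %in% inter, ]
      mat <- stats::reshape(sub[c("subject", "occasion", p)],
                            idvar = "subject", timevar = "occasion",
                            direction = "wide")
      icc <- icc_agreement(as.matrix(mat[, -1]))
      rows[[length(rows) + 1L]] <- data.frame(
        organ = org, parameter = p,
        wcv_intra = wcv(ti[[p]], ti$subject),
        wcv_inter = wcv(te[[p]], te$subject),
        icc = icc$icc, reliability = icc$reliability)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
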