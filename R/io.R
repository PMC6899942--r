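# Bit-stable CSV readers/writers for the tables the tools exchange.

#' Read an acquisition scheme from CSV
#'
#' Expects a header `b_s_mm2, T_ms, beta, n_repeats`. Every row is
#' validated against the hardware limits; malformed or infeasible rows are
#' reported by row number.
#'
#' @param path CSV file path.
#' @param hw [hardware_limits()] used for validation.
#' @param label Scheme label (defaults to the file name).
#' @return An [acquisition_scheme()].
#' @export
read_scheme <- function(path, hw = hardware_limits(), label = NULL) {
  df <- utils::read.csv(path)
  need <- c("b_s_mm2", "T_ms", "beta", "n_repeats")
  if (!all(need %in% names(df)))
    stop("scheme CSV must have columns: ", paste(need, collapse = ", "))
  bad <- which(!df$beta %in% c(0, 1) | df$b_s_mm2 < 0 | df$n_repeats < 1 |
                 !is.finite(df$b_s_mm2) | !is.finite(df$T_ms))
  if (length(bad))
    stop("malformed scheme rows: ", paste(bad, collapse = ", "))
  acquisition_scheme(b = df$b_s_mm2, T = df$T_ms, beta = df$beta,
                     n_repeats = df$n_repeats,
                     label = label %||% basename(path), hw = hw)
}

#' Write an acquisition scheme to CSV
#'
#' @param scheme An [acquisition_scheme()].
#' @param path Output file path.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  utils::write.csv(data.frame(b_s_mm2 = scheme$b, T_ms = scheme$T,
                              beta = scheme$beta,
                              n_repeats = scheme$n_repeats),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a signal curve to CSV
#'
#' Columns `b_s_mm2, T_ms, beta, signal`.
#' @param curve A `signal_curve`.
#' @param path Output file path.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(b_s_mm2 = curve$b, T_ms = curve$T,
                              beta = curve$beta, signal = curve$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a signal curve from CSV
#'
#' @param path CSV with columns `b_s_mm2, T_ms, beta, signal`.
#' @param normalized Whether the stored curve is already normalized.
#' @return A `signal_curve`.
#' @export
read_curve <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path)
  need <- c("b_s_mm2", "T_ms", "beta", "signal")
  if (!all(need %in% names(df)))
    stop("curve CSV must have columns: ", paste(need, collapse = ", "))
  signal_curve(data.frame(b = df$b_s_mm2, T = df$T_ms, beta = df$beta,
                          signal = df$signal),
               normalized = normalized, label = basename(path))
}

#' Write fit results to CSV
#'
#' One row per fit: label, D, f (\%), tau (ms), v (mm/s), S0, convergence
#' flag and residual norm.
#'
#' @param fits A single `fcivim` fit or a list of them.
#' @param path Output file path.
#' @param labels Optional labels (defaults to list names or indices).
#' @export
write_fit_results <- function(fits, path, labels = NULL) {
  if (inherits(fits, "fcivim")) fits <- list(fits)
  if (is.null(labels))
    labels <- names(fits) %||% as.character(seq_along(fits))
  rows <- lapply(seq_along(fits), function(i) {
    p <- coef(fits[[i]])
    data.frame(label = labels[i], D = p[["D"]], f_pct = p[["f"]] * 100,
               tau_ms = p[["tau"]], v_mm_s = p[["v"]], S0 = p[["S0"]],
               converged = fits[[i]]$converged,
               residual_norm = fits[[i]]$residual_norm)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
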