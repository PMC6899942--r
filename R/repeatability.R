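# Test-retest statistics for repeated ROI-wise parameter estimates:
# signal-drift correction, within-subject coefficient of variation,
# absolute-agreement intraclass correlation, protocol bias, and the
# echo-time compartment rescaling of the perfusion fraction.

#' Linear signal-drift detection and correction
#'
#' Fits ordinary least squares to the b = 0 signal of an ROI series versus
#' acquisition time. If the slope is significantly nonzero (two-sided
#' t-test, `p < alpha`), every signal in the series is divided by
#' `(a + b_slope * t)`; otherwise the series is returned unchanged. The
#' fit report is returned either way.
#'
#' @param series Data frame with columns `time` (s), `b` (s/mm^2) and
#'   `signal` (additional columns are carried through).
#' @param alpha Significance level for the slope test (default 0.05).
#' @return A list: `series` (corrected or original), `intercept`, `slope`,
#'   `p_value`, `corrected` (logical).
#' @export
drift_correct <- function(series, alpha = 0.05) {
  stopifnot(all(c("time", "b", "signal") %in% names(series)))
  if (is.unsorted(series$time)) stop("timestamps must be non-decreasing")
  b0 <- series[series$b == 0, ]
  if (nrow(b0) < 3)
    stop("need at least three b = 0 acquisitions to test for drift")
  if (diff(range(b0$time)) == 0)
    stop("degenerate series: all b = 0 timestamps are equal")
  fit <- stats::lm(signal ~ time, data = b0)
  coefs <- summary(fit)$coefficients
  a <- coefs[1, 1]; slope <- coefs[2, 1]; p <- coefs[2, 4]
  corrected <- is.finite(p) && p < alpha
  if (corrected) series$signal <- series$signal / (a + slope * series$time)
  list(series = series, intercept = a, slope = slope, p_value = p,
       corrected = corrected)
}

#' Within-subject coefficient of variation
#'
#' The default (`method = "rms"`) is the root mean square over subjects of
#' the per-subject coefficient of variation (within-subject SD divided by
#' within-subject mean), in percent. `method = "pooled"` returns the square
#' root of the mean within-subject variance divided by the grand mean.
#'
#' @param values Numeric vector of repeated measurements.
#' @param subject Subject identifier, parallel to `values`.
#' @param method `"rms"` or `"pooled"`.
#' @return wCV in percent.
#' @examples
#' wcv(c(10, 12, 20, 22), c(1, 1, 2, 2))  # 10.26
#' @export
wcv <- function(values, subject, method = c("rms", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(values) == length(subject))
  groups <- split(values, subject)
  if (length(groups) < 2) stop("need at least two subjects")
  if (any(vapply(groups, length, 1L) < 2))
    stop("need at least two measurements per subject")
  m <- vapply(groups, mean, numeric(1))
  s <- vapply(groups, stats::sd, numeric(1))
  if (method == "rms") {
    if (any(m == 0)) stop("zero within-subject mean")
    100 * sqrt(mean((s / m)^2))
  } else {
    gm <- mean(values)
    if (gm == 0) stop("zero grand mean")
    100 * sqrt(mean(s^2)) / gm
  }
}

#' Absolute-agreement average-measures intraclass correlation
#'
#' Two-way (subjects x measurement occasions) ANOVA decomposition;
#' absolute-agreement, average-of-k-measurements ICC with subjects treated
#' as random and occasions as fixed:
#' `ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' with MSR/MSC/MSE the subject/occasion/error mean squares and `n` the
#' number of subjects. Values >= 0.75 are flagged as good reliability;
#' negative estimates are unreliable and flagged `"n.a."`.
#'
#' @param mat Numeric matrix, subjects in rows, occasions in columns; no
#'   missing cells.
#' @return An object of class `icc_result`: `icc`, mean squares, `n`, `k`,
#'   and `reliability` (`"good"`, `"poor"`, or `"n.a."`).
#' @export
icc_agreement <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing cells are not supported (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3) stop("need at least three subjects")
  if (k < 2) stop("need at least two occasions")
  d <- data.frame(value = as.vector(mat),
                  subject = factor(rep(seq_len(n), k)),
                  occasion = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; anova.lm warns about its (unused)
  # F-tests when the two-way fit is essentially perfect
  ms <- suppressWarnings(
    stats::anova(stats::aov(value ~ subject + occasion, data = d)))
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["occasion", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  reliability <- if (!is.finite(icc) || icc < 0) "n.a."
                 else if (icc >= 0.75) "good" else "poor"
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k,
                 reliability = reliability),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC (two-way, absolute agreement, average of %d measurements): %.3f [%s]\n",
    x$k, x$icc, x$reliability))
  invisible(x)
}

#' Protocol bias relative to a reference protocol
#'
#' Mean over paired measurements of `100 * (ref - test) / ref`, the percent
#' deviation of a test protocol's parameter estimates from a reference
#' protocol assumed closest to truth.
#'
#' @param ref,test Paired numeric vectors; `ref` values must be nonzero.
#' @return Bias in percent.
#' @export
protocol_bias <- function(ref, test) {
  stopifnot(length(ref) == length(test))
  if (any(ref == 0)) stop("reference values must be nonzero")
  mean(100 * (ref - test) / ref)
}

#' Rescale a perfusion fraction to a different echo time
#'
#' The measured perfusion (signal) fraction depends on echo time because
#' tissue and blood relax at different T2. Treating the two compartments'
#' signals as scaling with `exp(-TE/T2)`, the compartment odds
#' `f / (1 - f)` rescale by
#' `exp((te_target - te_obs) * (1/t2_tissue - 1/t2_blood))`.
#'
#' @param f_obs Observed perfusion fraction at `te_obs`, in (0, 1).
#' @param te_obs,te_target Observed and target echo times, ms.
#' @param t2_tissue,t2_blood Compartment T2 values, ms (defaults: liver
#'   tissue 46 ms, venous blood 181 ms).
#' @return The perfusion fraction expected at `te_target`.
#' @examples
#' t2_adjust_f(0.45, te_obs = 122, te_target = 50)  # ~0.203
#' @export
t2_adjust_f <- function(f_obs, te_obs, te_target, t2_tissue = 46,
                        t2_blood = 181) {
  stopifnot(te_obs > 0, te_target > 0, t2_tissue > 0, t2_blood > 0)
  if (any(f_obs <= 0 | f_obs >= 1))
    stop("f_obs must lie strictly between 0 and 1")
  odds <- f_obs / (1 - f_obs) *
    exp((te_target - te_obs) * (1 / t2_tissue - 1 / t2_blood))
  odds / (1 + odds)
}
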