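#' Scanner gradient hardware limits
#'
#' Bundle of the gradient-system constraints under which diffusion-encoding
#' waveforms can be realized: peak gradient amplitude, slew rate, and the
#' usable range of diffusion times. Defaults correspond to a modern 1.5T
#' whole-body system with high-performance ("XQ"-class) gradients.
#'
#' @param g_max Peak gradient amplitude, mT/m.
#' @param slew_max Maximum slew rate, mT/m/ms.
#' @param t_min,t_max Allowed diffusion-time range, ms.
#' @param gamma Gyromagnetic ratio, rad/(s*T). Default is the proton value.
#' @return An object of class `hardware_limits`.
#' @examples
#' hw <- hardware_limits()
#' hw$g_max
#' @export
hardware_limits <- function(g_max = 45, slew_max = 200,
                            t_min = 40, t_max = 100,
                            gamma = 267.513e6) {
  stopifnot(g_max > 0, slew_max > 0, t_min > 0, t_max > 0, gamma > 0)
  if (t_min > t_max) stop("t_min must not exceed t_max")
  structure(list(g_max = g_max, slew_max = slew_max,
                 t_min = t_min, t_max = t_max, gamma = gamma),
            class = "hardware_limits")
}

#' @export
print.hardware_limits <- function(x, ...) {
  cat("Gradient hardware limits\n")
  cat(sprintf("  g_max:    %g mT/m\n", x$g_max))
  cat(sprintf("  slew_max: %g mT/m/ms\n", x$slew_max))
  cat(sprintf("  T range:  [%g, %g] ms\n", x$t_min, x$t_max))
  invisible(x)
}

check_T <- function(T, hw) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T))
    stop("T must be a single finite number (ms)")
  if (T < hw$t_min || T > hw$t_max)
    stop(sprintf("diffusion time T = %g ms outside hardware range [%g, %g] ms",
                 T, hw$t_min, hw$t_max))
  invisible(T)
}

check_beta <- function(beta) {
  if (!all(beta %in% c(0, 1)))
    stop("beta must be 0 (bipolar) or 1 (flow-compensated)")
  invisible(beta)
}
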