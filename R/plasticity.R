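# Homeostatic inhibitory synaptic plasticity (ISP): the C4 update rule and
# convergence diagnostics.

#' Plasticity (ISP) parameters
#'
#' The feedback-inhibition constant C4 of each node evolves as
#' \deqn{\tau \frac{dC_4}{dt} = \zeta_{inh} (\zeta_{pyr} - \rho)
#'   \left(\frac{C_4 - C_{4,min}}{C}\right)^\beta,}
#' driving the pyramidal rate toward the homeostatic target `rho`. `tau` is
#' the inverse learning rate (s), `beta` the soft-bound exponent, and
#' `c4_min` the lower bound (0 by default; the bounding factor then reduces
#' to C4/C). A hard clip at `c4_min` is applied after every integration step
#' to guard against finite-step overshoot.
#'
#' @param rho Target pyramidal firing rate, 1/s. Default 2.5.
#' @param tau Inverse learning rate, s. Default 2.
#' @param beta Bounding exponent. Default 1.
#' @param c4_min Lower bound of C4. Default 0.
#' @param enabled Logical; `FALSE` freezes C4 at its initial value.
#' @return An object of class `jr_plasticity`.
#' @export
jr_plasticity <- function(rho = 2.5, tau = 2, beta = 1, c4_min = 0,
                          enabled = TRUE) {
  stopifnot(tau > 0, rho >= 0, c4_min >= 0, beta >= 0)
  structure(list(rho = rho, tau = tau, beta = beta, c4_min = c4_min,
                 enabled = isTRUE(enabled)),
            class = "jr_plasticity")
}

#' ISP time derivative of C4
#'
#' @param c4 Current feedback-inhibition constant (must be >= `c4_min`).
#' @param zeta_pyr,zeta_inh Pyramidal and inhibitory firing rates, 1/s.
#' @param node A [jr_node()] object (supplies the local scale C).
#' @param plasticity A [jr_plasticity()] object.
#' @return dC4/dt (1/s).
#' @export
isp_derivative <- function(c4, zeta_pyr, zeta_inh, node = jr_node(),
                           plasticity = jr_plasticity()) {
  pp <- plasticity
  if (c4 < pp$c4_min) stop("c4 below its lower bound c4_min")
  zeta_inh * (zeta_pyr - pp$rho) * ((c4 - pp$c4_min) / node$C)^pp$beta / pp$tau
}

#' Time for a C4 trace to reach 63.2% of its total change
#'
#' The convergence timescale of the plasticity variable is the first time the
#' (ROI-averaged) C4 trace crosses
#' `c4_0 + (1 - 1/e) * (c4_inf - c4_0)`, where `c4_0` is the mean over the
#' first `baseline_window` seconds and `c4_inf` the mean over the last
#' `steady_window` seconds.
#'
#' @param c4_trace Numeric vector, the C4 time series.
#' @param dt Sampling interval of the trace, s.
#' @param baseline_window Length of the initial baseline, s. Default 2.
#' @param steady_window Length of the final steady window, s. Default 10.
#' @param tol Minimal |c4_inf - c4_0| regarded as a real change.
#' @return First-crossing time in seconds (measured from the start of the
#'   trace).
#' @export
convergence_time <- function(c4_trace, dt, baseline_window = 2,
                             steady_window = 10, tol = 1e-8) {
  n <- length(c4_trace)
  n0 <- max(1L, round(baseline_window / dt))
  n1 <- max(1L, round(steady_window / dt))
  if (n <= n0 + n1)
    stop("trace shorter than baseline_window + steady_window")
  c4_0 <- mean(c4_trace[seq_len(n0)])
  c4_inf <- mean(c4_trace[(n - n1 + 1):n])
  total <- c4_inf - c4_0
  if (abs(total) < tol) stop("degenerate trace: no measurable C4 change")
  thr <- c4_0 + (1 - exp(-1)) * total
  hit <- if (total > 0) which(c4_trace >= thr) else which(c4_trace <= thr)
  if (!length(hit)) stop("trace never reaches the 63.2% threshold")
  hit[1] * dt
}
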