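# Parameter containers and the elementary node operations: the firing-rate
# sigmoid, the alpha/gamma mixture, and the per-subpopulation PSP dynamics.

#' Sigmoid (potential-to-rate) parameters
#'
#' The average membrane potential of a population is converted into a mean
#' firing rate by the logistic sigmoid
#' \deqn{S(v) = \zeta_{max} / (1 + e^{-r (v - v_{th})}),}
#' bounded by the maximal rate `zeta_max`, with slope `slope` at the
#' half-activation threshold `v_th`.
#'
#' @param zeta_max Maximal firing rate (1/s). Default 5.
#' @param slope Sigmoid slope (1/mV). Default 0.56.
#' @param v_th Threshold potential (mV). Default 6.
#' @return An object of class `jr_sigmoid`.
#' @examples
#' sp <- jr_sigmoid()
#' sigmoid_rate(6, sp)  # half-maximum: 2.5
#' @export
jr_sigmoid <- function(zeta_max = 5, slope = 0.56, v_th = 6) {
  stopifnot(is.numeric(zeta_max), length(zeta_max) == 1L, zeta_max > 0,
            is.numeric(slope), length(slope) == 1L, slope > 0,
            is.numeric(v_th), length(v_th) == 1L, is.finite(v_th))
  structure(list(zeta_max = zeta_max, slope = slope, v_th = v_th),
            class = "jr_sigmoid")
}

#' Evaluate the firing-rate sigmoid
#'
#' @param v Membrane potential(s), mV. Must be finite.
#' @param sp A [jr_sigmoid()] object.
#' @return Firing rate(s) in (0, `zeta_max`), 1/s.
#' @export
sigmoid_rate <- function(v, sp = jr_sigmoid()) {
  if (!all(is.finite(v))) stop("non-finite membrane potential")
  sp$zeta_max / (1 + exp(-sp$slope * (v - sp$v_th)))
}

# derivative of the sigmoid, used by analytic Jacobians
sigmoid_rate_deriv <- function(v, sp = jr_sigmoid()) {
  e <- exp(-sp$slope * (v - sp$v_th))
  sp$zeta_max * sp$slope * e / (1 + e)^2
}

#' Subpopulation synaptic parameters
#'
#' PSP kernel constants of one neural-mass subpopulation: EPSP/IPSP maximal
#' amplitudes `A`/`B` (mV) and inverse time constants `a`/`b` (1/s). Two
#' presets are provided: `"alpha"` (A = 3.9, B = 26.4, a = 120, b = 60) and
#' `"gamma"`, whose gains are tied to its rate constants as
#' A = 32.5 a / 1000 and B = 440 b / 1000 (a = 660, b = 330), so the gamma
#' column is a time-rescaled copy of the alpha column with identical DC gains
#' A/a and B/b.
#'
#' @param preset `"alpha"`, `"gamma"`, or `"custom"`.
#' @param A,B,a,b Override any constant (required for `"custom"`).
#' @return An object of class `jr_subpop`.
#' @export
jr_subpop <- function(preset = c("alpha", "gamma", "custom"),
                      A = NULL, B = NULL, a = NULL, b = NULL) {
  preset <- match.arg(preset)
  if (preset == "alpha") {
    def <- list(A = 3.9, B = 26.4, a = 120, b = 60)
  } else if (preset == "gamma") {
    a0 <- if (is.null(a)) 660 else a
    b0 <- if (is.null(b)) 330 else b
    def <- list(A = 32.5 * a0 / 1000, B = 440 * b0 / 1000, a = a0, b = b0)
  } else {
    if (is.null(A) || is.null(B) || is.null(a) || is.null(b))
      stop("custom preset requires A, B, a and b")
    def <- list(A = A, B = B, a = a, b = b)
  }
  out <- modifyList(def, Filter(Negate(is.null),
                                list(A = A, B = B, a = a, b = b)))
  if (any(unlist(out) <= 0)) stop("subpopulation constants must be positive")
  structure(c(out, list(preset = preset)), class = "jr_subpop")
}

#' Node (cortical column) parameters
#'
#' Bundles the alpha and gamma subpopulations, the sigmoid, the local
#' connectivity constants C1..C4 (scaled by `C`), the subpopulation mixture
#' proportion `r_alpha`, and the model conventions.
#'
#' The mixture variables are
#' \deqn{x_k = r^\alpha x_k^\alpha + s\,(1 - r^\alpha)\, x_k^\gamma}
#' with `s = mixture_sign`. The package default is `s = +1` (a convex blend),
#' under which the single-node model reproduces the published regimes at all
#' mixtures (gamma-only slow/fast cycles, firing-rate clamping at
#' `r_alpha = 0.5`); `s = -1` gives the subtractive form that some
#' descriptions of the model print. `sigmoid_args` selects whether the
#' within-column sigmoids read the mixture variables (default, making both
#' subpopulations share the node-level drive) or each subpopulation's own
#' states.
#'
#' @param alpha,gamma [jr_subpop()] parameter sets.
#' @param sigmoid [jr_sigmoid()] parameters.
#' @param C Local connectivity scale (unitless), default 135.
#' @param c1,c2,c3,c4_init Connectivity constants; default C, 0.8 C, 0.25 C,
#'   0.25 C.
#' @param r_alpha Proportion of the alpha subpopulation, in \[0, 1\].
#' @param mixture_sign +1 (default) or -1; sign of the gamma contribution in
#'   the mixture variables.
#' @param sigmoid_args `"combined"` (default) or `"subpopulation"`.
#' @param coupling_scaled_by_Aa If `TRUE` (default), the inter-regional
#'   coupling term is premultiplied by A*a, i.e. it enters dy1/dt in the same
#'   units as the external input p; `FALSE` adds the raw rate sum instead,
#'   which at A*a ~ 468 makes coupling negligible for K of order 1 and
#'   suppresses every published network effect of K.
#' @return An object of class `jr_node`.
#' @export
jr_node <- function(alpha = jr_subpop("alpha"), gamma = jr_subpop("gamma"),
                    sigmoid = jr_sigmoid(), C = 135, c1 = C, c2 = 0.8 * C,
                    c3 = 0.25 * C, c4_init = 0.25 * C, r_alpha = 0.5,
                    mixture_sign = 1,
                    sigmoid_args = c("combined", "subpopulation"),
                    coupling_scaled_by_Aa = TRUE) {
  sigmoid_args <- match.arg(sigmoid_args)
  if (r_alpha < 0 || r_alpha > 1) stop("r_alpha must lie in [0, 1]")
  if (any(c(c1, c2, c3, c4_init) < 0)) stop("c1..c4_init must be >= 0")
  if (!mixture_sign %in% c(-1, 1)) stop("mixture_sign must be +1 or -1")
  structure(list(alpha = alpha, gamma = gamma, sigmoid = sigmoid, C = C,
                 c1 = c1, c2 = c2, c3 = c3, c4_init = c4_init,
                 r_alpha = r_alpha, mixture_sign = mixture_sign,
                 sigmoid_args = sigmoid_args,
                 coupling_scaled_by_Aa = coupling_scaled_by_Aa),
            class = "jr_node")
}

#' Combine subpopulation PSP triplets into node mixture variables
#'
#' @param alpha,gamma Numeric triplets (x0, x1, x2) in mV.
#' @param r_alpha Mixture proportion in \[0, 1\].
#' @param mixture_sign +1 (default, convex blend) or -1 (subtractive form).
#' @return The combined (x0, x1, x2) triplet.
#' @export
combine_subpop <- function(alpha, gamma, r_alpha, mixture_sign = 1) {
  if (r_alpha < 0 || r_alpha > 1) stop("r_alpha must lie in [0, 1]")
  r_alpha * alpha + mixture_sign * (1 - r_alpha) * gamma
}

#' Node firing rates from the mixture variables
#'
#' Given the combined triplet (x0, x1, x2), returns the pyramidal, excitatory
#' and inhibitory population rates
#' `zeta_pyr = S(x1 - x2)`, `zeta_exc = S(c1 x0)`, `zeta_inh = S(c3 x0)`.
#'
#' @param combined Numeric triplet (x0, x1, x2), mV.
#' @param node A [jr_node()] object.
#' @return Named vector `c(pyr, exc, inh)`, 1/s.
#' @export
firing_rates <- function(combined, node = jr_node()) {
  stopifnot(length(combined) == 3L)
  sp <- node$sigmoid
  c(pyr = sigmoid_rate(combined[2] - combined[3], sp),
    exc = sigmoid_rate(node$c1 * combined[1], sp),
    inh = sigmoid_rate(node$c3 * combined[1], sp))
}

#' Time derivatives of one subpopulation
#'
#' Reference (R) implementation of the six PSP-block equations of one
#' subpopulation, for a given sigmoid drive. `state` holds
#' (x0, y0, x1, y1, x2, y2); the sigmoid arguments `u0` (interneuron drive)
#' and `u_pyr` (pyramidal drive) are supplied by the caller so both the
#' combined- and own-argument conventions can be expressed.
#'
#' @param state Numeric length-6 state of the subpopulation.
#' @param subpop `"alpha"` or `"gamma"`.
#' @param u0,u_pyr Sigmoid arguments (mV): interneuron input potential and
#'   pyramidal membrane potential.
#' @param p_input External drive (1/s).
#' @param coupling Network input added to dy1/dt (>= 0; 0 for an isolated
#'   node).
#' @param node A [jr_node()] object (supplies constants and `c4` via
#'   `c4`).
#' @param c4 Current feedback-inhibition constant.
#' @return Numeric length-6 derivative vector.
#' @export
subpop_derivatives <- function(state, subpop = c("alpha", "gamma"), u0, u_pyr,
                               p_input, coupling = 0, node = jr_node(),
                               c4 = node$c4_init) {
  subpop <- match.arg(subpop)
  pp <- node[[subpop]]
  sp <- node$sigmoid
  cin <- if (node$coupling_scaled_by_Aa) pp$A * pp$a * coupling else coupling
  c(state[2],
    pp$A * pp$a * sigmoid_rate(u_pyr, sp) - 2 * pp$a * state[2] -
      pp$a^2 * state[1],
    state[4],
    pp$A * pp$a * (p_input + node$c2 * sigmoid_rate(node$c1 * u0, sp)) + cin -
      2 * pp$a * state[4] - pp$a^2 * state[3],
    state[6],
    pp$B * pp$b * c4 * sigmoid_rate(node$c3 * u0, sp) - 2 * pp$b * state[6] -
      pp$b^2 * state[5])
}

#' Full node derivative field (reference implementation)
#'
#' Deterministic time derivatives of the 12 PSP states (+ c4 when plasticity
#' is enabled) of a single node. Used as the cross-check oracle for the
#' compiled network integrator and by linearity tests.
#'
#' @param state Numeric vector of length 12 (alpha x0,y0,x1,y1,x2,y2 then
#'   gamma) or 13 (with c4 appended).
#' @param node A [jr_node()] object.
#' @param p_input External drive (1/s).
#' @param coupling Network input (1/s-scale), default 0.
#' @param plasticity A [jr_plasticity()] object or `NULL` for a frozen c4.
#' @return Derivative vector of the same length as `state`.
#' @export
node_derivatives <- function(state, node = jr_node(), p_input = 220,
                             coupling = 0, plasticity = NULL) {
  isp <- !is.null(plasticity) && isTRUE(plasticity$enabled)
  n_exp <- if (isp) 13L else 12L
  if (length(state) == 12L && isp)
    stop("state must include c4 as 13th element when plasticity is enabled")
  stopifnot(length(state) == n_exp)
  c4 <- if (isp) state[13] else node$c4_init
  ra <- node$r_alpha
  wg <- node$mixture_sign * (1 - ra)
  cx <- c(ra * state[1] + wg * state[7],
          ra * state[3] + wg * state[9],
          ra * state[5] + wg * state[11])
  d <- numeric(n_exp)
  for (s in c("alpha", "gamma")) {
    o <- if (s == "alpha") 0L else 6L
    if (node$sigmoid_args == "combined") {
      u0 <- cx[1]; upyr <- cx[2] - cx[3]
    } else {
      u0 <- state[o + 1]; upyr <- state[o + 3] - state[o + 5]
    }
    d[(o + 1):(o + 6)] <- subpop_derivatives(state[(o + 1):(o + 6)], s, u0,
                                             upyr, p_input, coupling, node,
                                             c4)
  }
  if (isp) {
    zr <- firing_rates(cx, node)
    d[13] <- isp_derivative(c4, zr[["pyr"]], zr[["inh"]], node, plasticity)
  }
  d
}

#' @export
print.jr_node <- function(x, ...) {
  cat("Jansen-Rit node parameters\n")
  cat(sprintf("  alpha: A=%.3g B=%.3g a=%.3g b=%.3g\n",
              x$alpha$A, x$alpha$B, x$alpha$a, x$alpha$b))
  cat(sprintf("  gamma: A=%.3g B=%.3g a=%.3g b=%.3g\n",
              x$gamma$A, x$gamma$B, x$gamma$a, x$gamma$b))
  cat(sprintf("  C=%g c1=%g c2=%g c3=%g c4_init=%g r_alpha=%g\n",
              x$C, x$c1, x$c2, x$c3, x$c4_init, x$r_alpha))
  cat(sprintf("  mixture_sign=%+d sigmoid_args=%s\n",
              x$mixture_sign, x$sigmoid_args))
  invisible(x)
}
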