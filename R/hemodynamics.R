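# Balloon-Windkessel haemodynamic forward model: pyramidal firing rates in,
# BOLD-like signals out.

#' Haemodynamic (Balloon-Windkessel) parameters
#'
#' @param tau_s Signal decay time constant, s.
#' @param tau_f Blood-inflow time constant, s.
#' @param tau_v Blood-volume time constant, s.
#' @param tau_q Deoxyhemoglobin time constant, s.
#' @param kappa Vessel stiffness exponent (Grubb exponent), in (0, 1\].
#' @param E0 Resting oxygen extraction fraction, in (0, 1).
#' @param V0 Resting venous blood volume fraction.
#' @param k1,k2,k3 BOLD kinetic constants.
#' @param dt Integration step of the haemodynamic ODEs, s.
#' @param TR Output repetition time, s.
#' @return An object of class `hemodynamic_params`.
#' @export
hemodynamic_params <- function(tau_s = 0.65, tau_f = 0.41, tau_v = 0.98,
                               tau_q = 0.98, kappa = 0.32, E0 = 0.4,
                               V0 = 0.04, k1 = 2.77, k2 = 0.2, k3 = 0.5,
                               dt = 0.01, TR = 2.08) {
  stopifnot(tau_s > 0, tau_f > 0, tau_v > 0, tau_q > 0,
            kappa > 0, kappa <= 1, E0 > 0, E0 < 1, V0 > 0, dt > 0, TR > 0)
  structure(list(tau_s = tau_s, tau_f = tau_f, tau_v = tau_v, tau_q = tau_q,
                 kappa = kappa, E0 = E0, V0 = V0, k1 = k1, k2 = k2, k3 = k3,
                 dt = dt, TR = TR),
            class = "hemodynamic_params")
}

#' Balloon-Windkessel derivatives
#'
#' State (s, f, v, q): vasodilatory signal, inflow, volume, deoxyhemoglobin.
#' \deqn{\dot s = z - s/\tau_s - (f-1)/\tau_f,\quad \dot f = s,}
#' \deqn{\dot v = (f - v^{1/\kappa})/\tau_v,\quad
#'       \dot q = \big(f\,\frac{1-(1-E_0)^{1/f}}{E_0}
#'                 - q\, v^{1/\kappa - 1}\big)/\tau_q.}
#' The outflow term of q uses the volume-normalized form
#' `q * v^(1/kappa) / v`, the standard Balloon outflow.
#'
#' @param state Numeric (s, f, v, q); `f`, `v`, `q` must be positive.
#' @param drive Neural drive z (pyramidal firing rate), 1/s.
#' @param hp A [hemodynamic_params()] object.
#' @return d(s, f, v, q)/dt.
#' @export
balloon_derivatives <- function(state, drive, hp = hemodynamic_params()) {
  s <- state[1]; f <- state[2]; v <- state[3]; q <- state[4]
  if (f <= 0 || v <= 0 || q <= 0)
    stop("invalid haemodynamic state: f, v, q must be positive")
  c(drive - s / hp$tau_s - (f - 1) / hp$tau_f,
    s,
    (f - v^(1 / hp$kappa)) / hp$tau_v,
    (f * (1 - (1 - hp$E0)^(1 / f)) / hp$E0 - q * v^(1 / hp$kappa - 1)) /
      hp$tau_q)
}

#' Closed-form resting/steady state of the Balloon model
#'
#' For a constant drive z the equilibrium is `s = tau_f * ...` solved from
#' zero derivatives: `f* = 1 + tau_f * z`, `v* = f*^kappa`,
#' `q* = f* (1-(1-E0)^(1/f*))/E0 * v* / f*` (i.e. the q that balances
#' inflow oxygen delivery against outflow), with `s* = 0`.
#'
#' @param drive Constant neural drive, 1/s.
#' @param hp A [hemodynamic_params()] object.
#' @return Named vector (s, f, v, q) and the associated BOLD value as
#'   attribute `"bold"`.
#' @export
balloon_steady_state <- function(drive, hp = hemodynamic_params()) {
  f <- 1 + hp$tau_f * drive
  v <- f^hp$kappa
  q <- f * (1 - (1 - hp$E0)^(1 / f)) / hp$E0 / v^(1 / hp$kappa - 1)
  st <- c(s = 0, f = f, v = v, q = q)
  attr(st, "bold") <- bold_observation(q, v, hp)
  st
}

bold_observation <- function(q, v, hp) {
  hp$V0 * (hp$k1 * (1 - q) + hp$k2 * (1 - q / v) + hp$k3 * (1 - v))
}

#' Simulate BOLD-like signals from firing rates
#'
#' Integrates the Balloon-Windkessel ODEs per region with explicit Euler at
#' `hp$dt` from the resting state (0, 1, 1, 1), driven by the pyramidal rate
#' traces, and samples the BOLD observation every TR.
#'
#' The default drive is the node-level (mixture) pyramidal rate. If `sim` is
#' a `jr_sim` recorded with `record_subpop = TRUE` and
#' `drive = "subpop_mixture"`, the drive is instead
#' `r_alpha * zeta_pyr_alpha + (1 - r_alpha) * zeta_pyr_gamma`.
#'
#' @param sim A `jr_sim` object, or a T x N matrix of rates.
#' @param fs Sampling rate of the drive when `sim` is a matrix, Hz.
#' @param hp A [hemodynamic_params()] object.
#' @param drive `"combined"` (default) or `"subpop_mixture"`.
#' @return An object of class `bold_sim`: list with `bold` (T' x N matrix at
#'   `1/TR` Hz), `fs`, and `hp`.
#' @export
simulate_bold <- function(sim, fs = NULL, hp = hemodynamic_params(),
                          drive = c("combined", "subpop_mixture")) {
  drive <- match.arg(drive)
  if (inherits(sim, "jr_sim")) {
    fs <- sim$fs
    z <- if (drive == "subpop_mixture") {
      if (is.null(sim$zeta_pyr_alpha))
        stop("subpop_mixture drive needs record_subpop = TRUE")
      ra <- sim$meta$node$r_alpha
      ra * sim$zeta_pyr_alpha + (1 - ra) * sim$zeta_pyr_gamma
    } else sim$zeta_pyr
  } else {
    if (is.null(fs)) stop("fs required when sim is a matrix")
    z <- as.matrix(sim)
  }
  n_in <- nrow(z); N <- ncol(z)
  t_end <- n_in / fs
  n_steps <- floor(t_end / hp$dt)
  state <- matrix(rep(c(0, 1, 1, 1), each = N), nrow = N)
  stride <- round(hp$TR / hp$dt)
  if (abs(hp$TR / hp$dt - stride) > 1e-9)
    stop("TR must be an integer multiple of the haemodynamic dt")
  n_out <- n_steps %/% stride
  bold <- matrix(NA_real_, n_out, N)
  rec <- 0L
  inv_k <- 1 / hp$kappa
  for (k in seq_len(n_steps)) {
    zi <- z[min(n_in, floor((k - 1) * hp$dt * fs) + 1L), ]
    s <- state[, 1]; f <- state[, 2]; v <- state[, 3]; q <- state[, 4]
    if (any(f <= 0 | v <= 0 | q <= 0))
      stop(sprintf("haemodynamic divergence at node %d",
                   which(f <= 0 | v <= 0 | q <= 0)[1]))
    ds <- zi - s / hp$tau_s - (f - 1) / hp$tau_f
    df <- s
    dv <- (f - v^inv_k) / hp$tau_v
    dq <- (f * (1 - (1 - hp$E0)^(1 / f)) / hp$E0 - q * v^(inv_k - 1)) /
      hp$tau_q
    state <- state + hp$dt * cbind(ds, df, dv, dq)
    if (k %% stride == 0L) {
      rec <- rec + 1L
      bold[rec, ] <- bold_observation(state[, 4], state[, 3], hp)
    }
  }
  structure(list(bold = bold, fs = 1 / hp$TR, hp = hp), class = "bold_sim")
}

#' @export
print.bold_sim <- function(x, ...) {
  cat(sprintf("bold_sim: %d region(s), %d volumes at TR = %.2f s\n",
              ncol(x$bold), nrow(x$bold), x$hp$TR))
  invisible(x)
}
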