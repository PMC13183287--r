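# Stochastic network simulation: protocol container, the external-input
# sampler, the Euler-Maruyama driver around the compiled core, and
# anti-aliased downsampling.

#' Simulation protocol
#'
#' @param dt Integration step, s. Default 0.001 (1 ms explicit Euler).
#' @param t_total Total simulated time, s.
#' @param t_discard Transient discarded from the outputs, s. Default 60.
#' @param p_mean Mean external input, 1/s. Default 220.
#' @param p_sd External input standard deviation, 1/s. Default 31.
#' @param K Global coupling. Default 0 (isolated nodes).
#' @param seed Integer seed; every random draw of the run derives from it.
#' @param noise If `FALSE` the input is the constant `p_mean`.
#' @param output_fs Output sampling rate after anti-aliased decimation, Hz.
#'   Must divide 1/dt. Default 200.
#' @param sde_scaling If `TRUE`, the per-step input fluctuations are scaled
#'   by 1/sqrt(dt) (diffusion convention); the default redraws
#'   Normal(p_mean, p_sd) each step and holds it over the step (sampled-input
#'   convention).
#' @return An object of class `jr_protocol`.
#' @export
jr_protocol <- function(dt = 1e-3, t_total = 180, t_discard = 60,
                        p_mean = 220, p_sd = 31, K = 0, seed = 1L,
                        noise = TRUE, output_fs = 200, sde_scaling = FALSE) {
  stopifnot(dt > 0, t_total > 0, t_discard >= 0, t_discard < t_total,
            p_sd >= 0, K >= 0, output_fs > 0)
  fs_in <- 1 / dt
  if (abs(fs_in / output_fs - round(fs_in / output_fs)) > 1e-9)
    stop("output_fs must divide the integration rate 1/dt")
  structure(list(dt = dt, t_total = t_total, t_discard = t_discard,
                 p_mean = p_mean, p_sd = p_sd, K = K, seed = as.integer(seed),
                 noise = isTRUE(noise), output_fs = output_fs,
                 sde_scaling = isTRUE(sde_scaling)),
            class = "jr_protocol")
}

#' Draw one step of external input
#'
#' i.i.d. Normal(p_mean, p_sd) per node; constant `p_mean` when noise is
#' disabled. Exposed mainly for testing the input statistics.
#'
#' @param n_nodes Number of regions.
#' @param protocol A [jr_protocol()].
#' @return Numeric vector of length `n_nodes` (1/s).
#' @export
draw_external_input <- function(n_nodes, protocol = jr_protocol()) {
  if (!protocol$noise || protocol$p_sd == 0) return(rep(protocol$p_mean,
                                                        n_nodes))
  rnorm(n_nodes, protocol$p_mean, protocol$p_sd)
}

node_pars_list <- function(node, plasticity) {
  list(A_alpha = node$alpha$A, B_alpha = node$alpha$B, a_alpha = node$alpha$a,
       b_alpha = node$alpha$b, A_gamma = node$gamma$A, B_gamma = node$gamma$B,
       a_gamma = node$gamma$a, b_gamma = node$gamma$b, C = node$C,
       c1 = node$c1, c2 = node$c2, c3 = node$c3, c4_init = node$c4_init,
       zeta_max = node$sigmoid$zeta_max, slope = node$sigmoid$slope,
       v_th = node$sigmoid$v_th, r_alpha = node$r_alpha,
       mixture_sign = node$mixture_sign,
       sigmoid_args = if (node$sigmoid_args == "combined") 0L else 1L,
       coupling_scaled_by_Aa = node$coupling_scaled_by_Aa,
       isp = isTRUE(plasticity$enabled), rho = plasticity$rho,
       tau = plasticity$tau, beta = plasticity$beta,
       c4_min = plasticity$c4_min)
}

#' Simulate the whole-brain (or single-node) model
#'
#' Integrates the full two-subpopulation network with explicit
#' Euler(-Maruyama) steps of `protocol$dt`, starting from all-zero PSP states
#' and `c4 = c4_init`, redrawing the external input every step. The first
#' `t_discard` seconds are dropped and all traces are anti-alias filtered and
#' decimated to `output_fs`.
#'
#' @param connectome A [connectome()], or `NULL` for a single isolated node.
#' @param node A [jr_node()] parameter set shared by all regions.
#' @param plasticity A [jr_plasticity()]; set `enabled = FALSE` to freeze C4.
#' @param protocol A [jr_protocol()].
#' @param record_subpop Also record the per-subpopulation pyramidal rates
#'   (used e.g. as an alternative haemodynamic drive).
#' @return An object of class `jr_sim` with elements `eeg`, `zeta_pyr`, `c4`
#'   (T x N matrices at `fs = output_fs`), `time` (seconds, relative to
#'   simulation onset), and `meta` (all parameters and the seed).
#' @export
jr_simulate <- function(connectome = NULL, node = jr_node(),
                        plasticity = jr_plasticity(),
                        protocol = jr_protocol(), record_subpop = FALSE) {
  W <- if (is.null(connectome)) matrix(0, 1, 1) else unclass(connectome)
  n_steps <- round(protocol$t_total / protocol$dt)
  pars <- node_pars_list(node, plasticity)
  set.seed(protocol$seed)
  raw <- jr_network_sim_cpp(W, pars, protocol$dt, n_steps, protocol$p_mean,
                            protocol$p_sd, protocol$K, protocol$noise,
                            protocol$sde_scaling, record_subpop)
  fs_in <- 1 / protocol$dt
  keep <- seq.int(round(protocol$t_discard * fs_in) + 1L, n_steps)
  ds <- function(m) {
    m <- m[keep, , drop = FALSE]
    apply(m, 2, downsample_signal, fs_in = fs_in, fs_out = protocol$output_fs)
  }
  out <- list(eeg = ds(raw$eeg), zeta_pyr = ds(raw$zeta_pyr),
              c4 = ds(raw$c4), fs = protocol$output_fs)
  if (record_subpop) {
    out$zeta_pyr_alpha <- ds(raw$zeta_pyr_alpha)
    out$zeta_pyr_gamma <- ds(raw$zeta_pyr_gamma)
  }
  out$time <- protocol$t_discard + seq_len(nrow(out$eeg)) / protocol$output_fs
  out$meta <- list(node = node, plasticity = plasticity, protocol = protocol,
                   n_nodes = nrow(W),
                   labels = if (is.null(connectome)) "node_1"
                            else rownames(connectome))
  class(out) <- "jr_sim"
  out
}

#' @export
print.jr_sim <- function(x, ...) {
  cat(sprintf("jr_sim: %d region(s), %.1f s at %g Hz (seed %d, K = %g)\n",
              ncol(x$eeg), nrow(x$eeg) / x$fs, x$fs,
              x$meta$protocol$seed, x$meta$protocol$K))
  cat(sprintf("  ISP %s; r_alpha = %g\n",
              if (x$meta$plasticity$enabled) "on" else "off",
              x$meta$node$r_alpha))
  invisible(x)
}

#' @export
summary.jr_sim <- function(object, ...) {
  pk <- tryCatch({
    w <- welch_psd(rowMeans(object$eeg), object$fs)
    peak_frequency(w$freq, w$psd, c(0.5, min(45, object$fs / 2 - 1)))
  }, error = function(e) NA_real_)
  out <- list(n_nodes = ncol(object$eeg),
              duration = nrow(object$eeg) / object$fs,
              mean_rate = mean(object$zeta_pyr),
              mean_c4 = colMeans(object$c4),
              peak_hz = pk)
  cat(sprintf("%d region(s), %.1f s; mean pyramidal rate %.3f 1/s; ",
              out$n_nodes, out$duration, out$mean_rate))
  cat(sprintf("grand-average EEG spectral peak %.1f Hz\n", out$peak_hz))
  invisible(out)
}

#' @export
plot.jr_sim <- function(x, nodes = 1, seconds = 5, ...) {
  i <- seq_len(min(round(seconds * x$fs), nrow(x$eeg)))
  graphics::matplot(x$time[i], x$eeg[i, nodes, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "EEG-like signal (mV)",
                    ...)
  invisible(x)
}

#' Anti-aliased decimation
#'
#' Low-pass filters (zero-phase Butterworth, cutoff 0.8 of the target
#' Nyquist) and then keeps every (fs_in/fs_out)-th sample. Identity when the
#' two rates are equal.
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Input and output sampling rates; their ratio must be
#'   an integer.
#' @return The decimated signal.
#' @export
downsample_signal <- function(x, fs_in, fs_out) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9) stop("fs_in / fs_out must be an integer")
  r <- round(r)
  if (r == 1L) return(x)
  bf <- signal::butter(4, 0.8 / r, type = "low")
  # filter around the mean so a DC level passes through without edge
  # transients
  m <- mean(x)
  y <- signal::filtfilt(bf, x - m) + m
  y[seq.int(1L, length(y), by = r)]
}
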