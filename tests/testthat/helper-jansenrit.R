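# Shared helpers: cached simulations (several tests reuse the same runs) and
# a Welch-peak shortcut.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

welch_peak_of <- function(x, fs, range = c(0.5, 60)) {
  w <- welch_psd(x, fs)
  peak_frequency(w$freq, w$psd, range)
}

# single-node run with the published protocol defaults
node_run <- function(r_alpha, p_mean, isp = FALSE, rho = 2.5, noise = FALSE,
                     t_total = 120, t_discard = 60, seed = 1, tau = 2) {
  jr_simulate(NULL, jr_node(r_alpha = r_alpha),
              jr_plasticity(rho = rho, tau = tau, enabled = isp),
              jr_protocol(t_total = t_total, t_discard = t_discard,
                          p_mean = p_mean, noise = noise, seed = seed))
}
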