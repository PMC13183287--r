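# Run configuration: structured defaults mirroring the published parameter
# table, YAML round-trip, and strict validation.

jr_config_defaults <- function() {
  list(
    model = list(
      A_alpha = 3.9, B_alpha = 26.4, a_alpha = 120, b_alpha = 60,
      a_gamma = 660, b_gamma = 330,
      zeta_max = 5, slope = 0.56, v_th = 6,
      C = 135, r_alpha = 0.5, mixture_sign = 1,
      sigmoid_args = "combined", coupling_scaled_by_Aa = TRUE
    ),
    plasticity = list(
      enabled = TRUE, rho = 2.5, tau = 2, beta = 1, c4_min = 0
    ),
    protocol = list(
      dt = 0.001, t_total = 180, t_discard = 60, p_mean = 220, p_sd = 31,
      K = 0, seed = 1, noise = TRUE, output_fs = 200, sde_scaling = FALSE
    ),
    hemodynamics = list(
      tau_s = 0.65, tau_f = 0.41, tau_v = 0.98, tau_q = 0.98, kappa = 0.32,
      E0 = 0.4, V0 = 0.04, k1 = 2.77, k2 = 0.2, k3 = 0.5, dt = 0.01,
      TR = 2.08
    ),
    bands = list(
      delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
      beta = c(13, 30), gamma = c(30, 40)
    )
  )
}

validate_config <- function(cfg) {
  with(cfg$model, {
    if (r_alpha < 0 || r_alpha > 1) stop("model.r_alpha out of [0, 1]")
    if (zeta_max <= 0) stop("model.zeta_max must be positive")
    if (any(c(A_alpha, B_alpha, a_alpha, b_alpha, a_gamma, b_gamma) <= 0))
      stop("model synaptic constants must be positive")
  })
  with(cfg$plasticity, {
    if (rho < 0) stop("plasticity.rho must be >= 0")
    if (tau <= 0) stop("plasticity.tau must be positive")
    if (c4_min < 0) stop("plasticity.c4_min must be >= 0")
  })
  with(cfg$protocol, {
    if (dt <= 0) stop("protocol.dt must be positive")
    if (t_discard >= t_total) stop("protocol.t_discard must be < t_total")
    if (p_sd < 0) stop("protocol.p_sd must be >= 0")
  })
  with(cfg$hemodynamics, {
    if (E0 <= 0 || E0 >= 1) stop("hemodynamics.E0 must lie in (0, 1)")
    if (kappa <= 0 || kappa > 1) stop("hemodynamics.kappa out of (0, 1]")
  })
  for (b in names(cfg$bands)) {
    e <- cfg$bands[[b]]
    if (length(e) != 2 || e[1] <= 0 || e[2] <= e[1])
      stop("bands.", b, " must be c(lo, hi) with 0 < lo < hi")
  }
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML file of overrides on top of the full default parameter set
#' (the published defaults: sigmoid 5/0.56/6, alpha column 3.9/26.4/120/60,
#' gamma rate constants 660/330 with tied gains, C = 135, input 220 +/- 31,
#' rho = 2.5, tau = 2, beta = 1, dt = 1 ms, ...). Unknown keys and
#' out-of-range values raise descriptive errors. An empty or missing-file
#' path of `NULL` yields the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated nested list of class `jr_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- jr_config_defaults()
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (is.null(over)) over <- list()
    for (sec in names(over)) {
      if (!sec %in% names(cfg))
        stop("unknown config section: ", sec)
      for (key in names(over[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          stop("unknown config key: ", sec, ".", key)
        val <- over[[sec]][[key]]
        tmpl <- cfg[[sec]][[key]]
        if (is.numeric(tmpl) && !is.numeric(val))
          stop("type mismatch for ", sec, ".", key, ": expected numeric")
        if (is.logical(tmpl) && !is.logical(val))
          stop("type mismatch for ", sec, ".", key, ": expected logical")
        cfg[[sec]][[key]] <- val
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = "jr_config")
}

#' @rdname load_config
#' @param cfg A `jr_config` object.
#' @param path Output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build parameter objects from a configuration
#'
#' @param cfg A `jr_config` from [load_config()].
#' @return List with `node`, `plasticity`, `protocol`, `hemodynamics`.
#' @export
config_to_params <- function(cfg) {
  m <- cfg$model
  node <- jr_node(
    alpha = jr_subpop("custom", A = m$A_alpha, B = m$B_alpha, a = m$a_alpha,
                      b = m$b_alpha),
    gamma = jr_subpop("gamma", a = m$a_gamma, b = m$b_gamma),
    sigmoid = jr_sigmoid(m$zeta_max, m$slope, m$v_th),
    C = m$C, r_alpha = m$r_alpha, mixture_sign = m$mixture_sign,
    sigmoid_args = m$sigmoid_args,
    coupling_scaled_by_Aa = m$coupling_scaled_by_Aa)
  pl <- cfg$plasticity
  pr <- cfg$protocol
  hp <- cfg$hemodynamics
  list(node = node,
       plasticity = jr_plasticity(pl$rho, pl$tau, pl$beta, pl$c4_min,
                                  pl$enabled),
       protocol = jr_protocol(pr$dt, pr$t_total, pr$t_discard, pr$p_mean,
                              pr$p_sd, pr$K, pr$seed, pr$noise,
                              pr$output_fs, pr$sde_scaling),
       hemodynamics = hemodynamic_params(hp$tau_s, hp$tau_f, hp$tau_v,
                                         hp$tau_q, hp$kappa, hp$E0, hp$V0,
                                         hp$k1, hp$k2, hp$k3, hp$dt, hp$TR))
}

#' Write a simulation result with a JSON manifest
#'
#' Writes the EEG, firing-rate and C4 traces as CSV files next to `path`
#' (suffixes `_eeg.csv`, `_rate.csv`, `_c4.csv`) plus a JSON sidecar
#' `<path>.json` recording the resolved parameters, the seed and MD5
#' checksums, so a run is reproducible from its manifest alone.
#'
#' @param sim A `jr_sim`.
#' @param path Output stem (no extension).
#' @return The manifest (invisibly), also written to `<path>.json`.
#' @export
write_result <- function(sim, path) {
  stopifnot(inherits(sim, "jr_sim"))
  files <- c(eeg = paste0(path, "_eeg.csv"),
             rate = paste0(path, "_rate.csv"),
             c4 = paste0(path, "_c4.csv"))
  utils::write.csv(as.data.frame(sim$eeg), files["eeg"], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$zeta_pyr), files["rate"],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$c4), files["c4"], row.names = FALSE)
  manifest <- list(
    package = "jansenrit",
    version = as.character(utils::packageVersion("jansenrit")),
    fs = sim$fs,
    n_nodes = sim$meta$n_nodes,
    seed = sim$meta$protocol$seed,
    protocol = sim$meta$protocol[setdiff(names(sim$meta$protocol), NULL)],
    plasticity = unclass(sim$meta$plasticity),
    node = list(r_alpha = sim$meta$node$r_alpha,
                mixture_sign = sim$meta$node$mixture_sign,
                sigmoid_args = sim$meta$node$sigmoid_args,
                C = sim$meta$node$C),
    files = as.list(files),
    md5 = as.list(tools::md5sum(unname(files)))
  )
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
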