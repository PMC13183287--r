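# Deterministic test-signal generators: Gaussian series with a prescribed
# correlation structure and amplitude-modulated carrier pairs. Together with
# synthetic_connectome() these make every pipeline stage testable offline.

#' Gaussian series with a target correlation matrix
#'
#' Draws `n_samples` i.i.d. Gaussian vectors with correlation `target_fc`
#' (via the Cholesky/eigen factor), so the sample correlation converges to
#' the target as the series grows.
#'
#' @param target_fc Positive semidefinite correlation matrix (N x N).
#' @param n_samples Number of time points.
#' @param seed Integer seed (local RNG).
#' @return `n_samples x N` matrix.
#' @export
make_gaussian_fc_series <- function(target_fc, n_samples, seed = 1L) {
  target_fc <- as.matrix(target_fc)
  if (!isTRUE(all.equal(target_fc, t(target_fc))))
    stop("target correlation matrix must be symmetric")
  ev <- eigen(target_fc, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("target correlation matrix is not positive semidefinite")
  vals <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(vals), nrow = length(vals))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  z <- matrix(rnorm(n_samples * nrow(target_fc)), n_samples)
  z %*% t(A)
}

#' Pair of carriers with partially shared amplitude modulation
#'
#' Two sinusoidal carriers whose slow amplitude envelopes share a fraction
#' `shared_fraction` of their variance; the expected envelope correlation
#' increases monotonically with that fraction. Exercises the band-pass ->
#' Hilbert-envelope -> correlation pipeline with a known ground truth.
#'
#' @param carrier_hz Carrier frequency (Hz).
#' @param env_hz Envelope frequency (Hz); must be below `carrier_hz / 4`.
#' @param shared_fraction Fraction of shared envelope variance, in \[0, 1\].
#' @param fs Sampling rate (Hz); must resolve the carrier.
#' @param n_samples Number of samples.
#' @param seed Integer seed (local RNG; randomizes phases).
#' @return `n_samples x 2` matrix.
#' @export
make_am_pair <- function(carrier_hz = 10, env_hz = 1, shared_fraction = 1,
                         fs = 200, n_samples = 4000, seed = 1L) {
  if (env_hz >= carrier_hz / 4)
    stop("envelope frequency must be below carrier_hz / 4")
  if (fs <= 2 * carrier_hz) stop("aliasing: fs must exceed 2 * carrier_hz")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  t <- seq_len(n_samples) / fs
  shared <- sin(2 * pi * env_hz * t + stats::runif(1, 0, 2 * pi))
  # private modulations at incommensurate rates, so they are uncorrelated
  # with the shared component and with each other over the record
  own_hz <- env_hz * c(0.713, 1.317)
  own <- sapply(own_hz, function(f)
    sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)))
  w <- sqrt(shared_fraction)
  v <- sqrt(1 - shared_fraction)
  env <- cbind(1.5 + w * shared + v * own[, 1],
               1.5 + w * shared + v * own[, 2])
  ph <- stats::runif(2, 0, 2 * pi)
  cbind(env[, 1] * sin(2 * pi * carrier_hz * t + ph[1]),
        env[, 2] * sin(2 * pi * carrier_hz * t + ph[2]))
}
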