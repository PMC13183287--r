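# Spectral machinery shared by simulated and empirical signals: Bessel
# band-pass filtering, Hilbert envelopes, Welch power spectra, relative band
# power and peak frequency.

#' Canonical EEG frequency bands
#'
#' delta (0.5-4), theta (4-8), alpha (8-13), beta (13-30), gamma (30-40) Hz.
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(0.5, 4, 8, 13, 30),
             hi = c(4, 8, 13, 30, 40),
             stringsAsFactors = FALSE)
}

# 3rd-order analog Bessel low-pass prototype, phase-normalized: poles are the
# roots of the reverse Bessel polynomial s^3 + 6 s^2 + 15 s + 15, scaled by
# 15^(1/3) so the cutoff parameter is meaningful (unit characteristic
# frequency, DC gain 1).
bessel_prototype <- function(order = 3) {
  if (order != 3) stop("only the 3rd-order Bessel prototype is provided")
  pole <- polyroot(c(15, 15, 6, 1)) / 15^(1 / 3)
  signal::Zpg(zero = numeric(0), pole = pole, gain = 1)
}

# digital Bessel filter via analog prototype -> band transform -> bilinear
bessel_filter <- function(W, fs, type = c("pass", "low", "high")) {
  type <- match.arg(type)
  Wn <- W / (fs / 2)
  if (any(Wn <= 0) || any(Wn >= 1)) stop("band edges must lie in (0, fs/2)")
  T <- 2
  Wp <- 2 / T * tan(pi * Wn / T)
  proto <- bessel_prototype(3)
  analog <- if (type == "pass") {
    signal::sftrans(proto, W = Wp, stop = FALSE)
  } else if (type == "low") {
    signal::sftrans(proto, W = Wp, stop = FALSE)
  } else {
    signal::sftrans(proto, W = Wp, stop = TRUE)
  }
  signal::as.Arma(signal::bilinear(analog, T = T))
}

#' Zero-phase Bessel band-pass filter
#'
#' 3rd-order Bessel band-pass applied forward and backward
#' (zero net phase, squared magnitude response).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz; must exceed 2 * `hi`.
#' @param lo,hi Band edges, Hz.
#' @return The filtered signal.
#' @export
bandpass_filter <- function(x, fs, lo, hi) {
  stopifnot(lo > 0, hi > lo)
  if (fs <= 2 * hi) stop("band extends beyond the Nyquist frequency")
  flt <- bessel_filter(c(lo, hi), fs, "pass")
  signal::filtfilt(flt$b, flt$a, x)
}

#' Amplitude envelope of a band-limited signal
#'
#' Magnitude of the analytic signal (FFT-based Hilbert transform), then a
#' zero-phase 3rd-order Butterworth high-pass at `highpass` Hz to remove the
#' DC level of the envelope.
#'
#' @param x Numeric band-limited signal.
#' @param fs Sampling rate, Hz.
#' @param highpass Envelope high-pass cutoff, Hz (default 0.5; `NULL` skips
#'   it).
#' @return The (high-passed) envelope.
#' @export
signal_envelope <- function(x, fs, highpass = 0.5) {
  n <- length(x)
  if (n < 10 * fs)
    warning("signal shorter than 10 s; envelope estimates may be unstable")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  if (is.null(highpass)) return(env)
  bf <- signal::butter(3, highpass / (fs / 2), type = "high")
  signal::filtfilt(bf, env)
}

#' Welch power spectral density
#'
#' Hann-tapered segments of `window_sec` seconds with 50% overlap, mean
#' removed per segment; one-sided density normalized so that
#' `sum(psd) * df` equals the signal variance for a stationary signal.
#' With the default 2-s windows the frequency resolution is 0.5 Hz.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param window_sec Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (length(x) < nw) stop("signal shorter than one Welch window")
  hop <- max(1L, round(nw * (1 - overlap)))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))  # Hann
  starts <- seq.int(1L, length(x) - nw + 1L, by = hop)
  acc <- numeric(nw)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  scale <- fs * sum(w^2) * length(starts)
  half <- nw %/% 2 + 1L
  psd <- acc[seq_len(half)] / scale
  if (nw %% 2 == 0) psd[2:(half - 1L)] <- 2 * psd[2:(half - 1L)]
  else psd[2:half] <- 2 * psd[2:half]
  list(freq = (seq_len(half) - 1) * fs / nw, psd = psd)
}

#' Relative band power
#'
#' Integrates the PSD over each band (half-open bins `[lo, hi)`) and divides
#' by the total power over `total_range` (default 0.5-30 Hz).
#'
#' @param freq,psd Frequency grid and density, e.g. from [welch_psd()].
#' @param bands A data.frame like [band_definitions()] (columns `name`, `lo`,
#'   `hi`).
#' @param total_range Normalization range, Hz.
#' @return Named vector of band-power fractions.
#' @export
relative_band_power <- function(freq, psd, bands = band_definitions(),
                                total_range = c(0.5, 30)) {
  stopifnot(length(freq) == length(psd))
  tot_sel <- freq >= total_range[1] & freq < total_range[2]
  total <- sum(psd[tot_sel])
  if (total <= 0) stop("zero total power in the normalization range")
  out <- vapply(seq_len(nrow(bands)), function(i) {
    sel <- freq >= bands$lo[i] & freq < bands$hi[i]
    sum(psd[sel]) / total
  }, numeric(1))
  names(out) <- bands$name
  out
}

#' Peak frequency of a spectrum
#'
#' Frequency of the maximal density within `range`; ties are broken toward
#' the lower frequency (the first maximal bin on the ascending grid).
#'
#' @param freq,psd Frequency grid and density.
#' @param range Numeric length-2 search interval, Hz.
#' @return Peak frequency, Hz.
#' @export
peak_frequency <- function(freq, psd, range = c(0.5, 45)) {
  sel <- freq >= range[1] & freq <= range[2]
  if (!any(sel)) stop("empty search range")
  f <- freq[sel]
  f[which.max(psd[sel])]
}

#' Normalized power spectrum
#'
#' PSD divided by its maximum (scale-invariant summary used for spectral
#' heat maps).
#'
#' @param psd Density values.
#' @return `psd / max(psd)`.
#' @export
normalized_psd <- function(psd) {
  m <- max(psd)
  if (m <= 0) stop("cannot normalize an all-zero spectrum")
  psd / m
}
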