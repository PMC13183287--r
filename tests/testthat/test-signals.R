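# Filtering, envelopes, Welch spectra, band power and peak frequency.

test_that("Bessel band-pass keeps the band and rejects out-of-band energy", {
  fs <- 200
  t <- seq(1 / fs, 60, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  expect_equal(sd(bandpass_filter(x10, fs, 8, 13)) / sd(x10), 1,
               tolerance = 0.05)
  # 10 Hz through the delta band: attenuated by more than 90%
  expect_lt(sd(bandpass_filter(x10, fs, 0.5, 4)) / sd(x10), 0.1)
  expect_equal(bandpass_filter(rep(0, 1000), fs, 8, 13), rep(0, 1000))
  expect_error(bandpass_filter(x10, fs, 8, 150), "Nyquist")
  # energy one octave outside the band is at least 20 dB down
  x26 <- sin(2 * pi * 26 * t)
  gain <- sd(bandpass_filter(x26, fs, 8, 13)) / sd(x26)
  expect_lt(20 * log10(gain), -20)
})

test_that("zero-phase filtering leaves a symmetric pulse symmetric", {
  fs <- 200
  n <- 4001
  pulse <- exp(-((seq_len(n) - 2001) / 80)^2)
  y <- bandpass_filter(pulse, fs, 4, 8)
  expect_gt(cor(y, rev(y)), 0.999)
})

test_that("Hilbert envelope recovers a known amplitude modulation", {
  fs <- 200
  t <- seq(1 / fs, 60, by = 1 / fs)
  A <- 1 + 0.5 * sin(2 * pi * 1 * t)
  x <- A * sin(2 * pi * 10 * t)
  env <- signal_envelope(x, fs)
  bf <- signal::butter(3, 0.5 / (fs / 2), type = "high")
  A_hp <- signal::filtfilt(bf, A)
  expect_gt(cor(env, A_hp), 0.95)
  # constant-amplitude carrier: envelope is flat, hence ~0 after high-pass
  # evaluated away from the record edges, where the analytic signal rolls off
  env_c <- signal_envelope(sin(2 * pi * 10 * t), fs)
  core <- seq(2 * fs, length(env_c) - 2 * fs)
  expect_lt(sd(env_c[core]), 0.02)
  expect_equal(signal_envelope(rep(0, 3000), fs), rep(0, 3000),
               tolerance = 1e-12)
  expect_warning(signal_envelope(sin(2 * pi * 10 * t[1:400]), fs), "10 s")
})

test_that("Welch PSD localizes tones and integrates to the variance", {
  fs <- 200
  t <- seq(1 / fs, 120, by = 1 / fs)
  w <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(diff(w$freq[1:2]), 0.5)
  expect_equal(w$freq[which.max(w$psd)], 10)
  expect_true(all(w$psd >= 0))
  # two tones give two resolved peaks
  w2 <- welch_psd(sin(2 * pi * 10 * t) + 0.8 * sin(2 * pi * 40 * t), fs)
  top2 <- sort(w2$freq[order(-w2$psd)[1:2]])
  expect_equal(top2, c(10, 40))
  # white noise: flat density whose integral matches the variance
  set.seed(5)
  xn <- rnorm(fs * 200)
  wn <- welch_psd(xn, fs)
  expect_equal(sum(wn$psd) * 0.5, var(xn), tolerance = 0.05)
  band_means <- tapply(wn$psd[-1], cut(wn$freq[-1], 8), mean)
  expect_lt(max(band_means) / min(band_means), 1.35)
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("relative band power normalizes against 0.5-30 Hz and sums to one", {
  fs <- 200
  t <- seq(1 / fs, 120, by = 1 / fs)
  w <- welch_psd(sin(2 * pi * 10 * t), fs)
  rbp <- relative_band_power(w$freq, w$psd)
  expect_gt(rbp[["alpha"]], 0.97)
  expect_lt(sum(rbp[c("delta", "theta", "beta")]), 0.03)
  # the four bands partition 0.5-30 Hz, so their fractions sum to 1
  set.seed(6)
  wmix <- welch_psd(rnorm(fs * 60), fs)
  four <- band_definitions()[1:4, ]
  expect_equal(sum(relative_band_power(wmix$freq, wmix$psd, four)), 1,
               tolerance = 1e-12)
  # synthetic 1/f spectrum against a direct summation oracle
  freq <- seq(0, 50, by = 0.5)
  psd <- c(0, 1 / freq[-1])
  got <- relative_band_power(freq, psd, four)
  tot <- sum(psd[freq >= 0.5 & freq < 30])
  for (i in 1:4) {
    sel <- freq >= four$lo[i] & freq < four$hi[i]
    expect_equal(got[[four$name[i]]], sum(psd[sel]) / tot, tolerance = 1e-12)
  }
  expect_error(relative_band_power(freq, 0 * psd), "zero total")
})

test_that("peak frequency respects the range and low-frequency tie-break", {
  freq <- seq(0, 50, by = 0.5)
  psd <- numeric(length(freq)); psd[freq == 10] <- 1
  expect_equal(peak_frequency(freq, psd), 10)
  expect_equal(peak_frequency(freq, rep(1, length(freq)), c(4, 30)), 4)
  psd2 <- numeric(length(freq)); psd2[freq == 3] <- 2; psd2[freq == 10] <- 1
  expect_equal(peak_frequency(freq, psd2), 3)
  expect_error(peak_frequency(freq, psd, c(60, 70)), "empty")
})

test_that("normalized spectra are invariant to positive rescaling", {
  set.seed(3)
  fs <- 200
  x <- rnorm(fs * 30)
  w1 <- welch_psd(x, fs)
  w2 <- welch_psd(3.7 * x, fs)
  expect_equal(normalized_psd(w1$psd), normalized_psd(w2$psd),
               tolerance = 1e-10)
  expect_error(normalized_psd(rep(0, 5)), "all-zero")
})
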