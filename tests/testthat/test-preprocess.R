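test_that("band-pass blocks DC and matches its designed magnitude response", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  central <- (2 * fs):(8 * fs)

  # DC is in the high-pass stop band
  y <- bandpass_filter(rep(1, length(t)), fs)
  expect_lt(max(abs(y[central])), 0.01)

  # in-band and stop-band sinusoids against the transfer-function oracle
  # (amplitude read off as sqrt(2) * RMS, which is phase-robust)
  for (f0 in c(1, 2, 8)) {
    y <- bandpass_filter(sin(2 * pi * f0 * t), fs)
    amp <- sqrt(2 * mean(y[central]^2))
    expect_equal(amp, bp_mag2(f0, fs), tolerance = 0.01)
  }
  y30 <- bandpass_filter(sin(2 * pi * 30 * t), fs)
  amp30 <- sqrt(2 * mean(y30[central]^2))
  expect_lt(amp30, 0.012)  # both stop bands are specified at -20 dB one-way
})

test_that("band-pass is zero-phase and linear", {
  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 1.5 * t)
  y <- bandpass_filter(x, fs)
  central <- (3 * fs):(7 * fs)
  # the cross-correlation between input and output peaks at zero lag
  lags <- -10:10
  cc <- vapply(lags, function(L)
    sum(x[central] * y[central + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)

  x2 <- cos(2 * pi * 3 * t)
  lin <- bandpass_filter(2 * x + 3 * x2, fs)
  sup <- 2 * bandpass_filter(x, fs) + 3 * bandpass_filter(x2, fs)
  expect_equal(lin, sup, tolerance = 1e-8)
})

test_that("band-pass rejects invalid designs and too-short signals", {
  expect_error(bandpass_filter(rnorm(100), fs = 20), "band edge")
  expect_error(bandpass_filter(rnorm(10), fs = 256), "too short")
})

test_that("moving average: constants, impulse plateau, boxcar attenuation", {
  expect_equal(moving_average(rep(5, 100), 50, 1000), rep(5, 100))

  imp <- c(rep(0, 500), 1, rep(0, 500))
  y <- moving_average(imp, 50, 1000)  # 51-sample window (forced odd)
  expect_equal(sum(y > 0), 51)
  expect_equal(max(y), 1 / 51)
  expect_equal(unique(round(y[y > 0], 12)), round(1 / 51, 12))

  fs <- 1000
  t <- (0:(2 * fs - 1)) / fs
  x <- sin(2 * pi * 100 * t)
  y <- moving_average(x, 10, fs)  # 11-sample boxcar
  amp <- sqrt(2 * mean(y[500:1500]^2))
  expect_equal(amp, boxcar_mag(100, fs, 11), tolerance = 0.02)

  # sub-sample window returns the input with a notice
  expect_message(out <- moving_average(1:10, 0.4, 1000), "unchanged")
  expect_identical(out, 1:10)
})

test_that("derivatives recover calculus on ramps, sines and constants", {
  fs <- 256
  t <- (0:(5 * fs - 1)) / fs
  d <- compute_derivatives(3 * t, fs)
  interior <- (fs):(4 * fs)
  expect_equal(max(abs(d$d1[interior] - 3)), 0, tolerance = 1e-6)
  expect_equal(max(abs(d$d2[interior])), 0, tolerance = 1e-4)

  d <- compute_derivatives(sin(2 * pi * t), fs)
  expect_lt(max(abs(d$d1[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            0.03 * 2 * pi)

  d <- compute_derivatives(rep(2, 5 * fs), fs)
  expect_equal(d$d1, rep(0, 5 * fs))
  expect_equal(d$d3, rep(0, 5 * fs))
})

test_that("Fourier resampling: length contract, identity, band-limited fidelity", {
  x <- rnorm(2560)
  expect_length(resample_fourier(x, 256, 75), 750)
  expect_identical(resample_fourier(x, 256, 256), x)

  fs <- 256
  t <- (0:(10 * fs - 1)) / fs
  y <- resample_fourier(sin(2 * pi * t), fs, 75)
  t75 <- (seq_along(y) - 1) / 75
  central <- which(t75 > 1 & t75 < 9)
  rmse <- sqrt(mean((y[central] - sin(2 * pi * t75[central]))^2))
  expect_lt(rmse, 0.01)
})

test_that("full chain preserves pulse amplitude and peak positions", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 20, fs = 256))
  proc <- preprocess_signal(g$signal)
  central <- (5 * 256):(15 * 256)
  p2p_raw <- diff(range(g$signal$samples[central]))
  p2p_filt <- diff(range(proc$ppg[central]))
  expect_lt(abs(p2p_filt - p2p_raw) / p2p_raw, 0.05)

  # systolic peak of a clean pulse moves less than one sample
  raw_peak <- central[1] + which.max(g$signal$samples[central]) - 1
  win <- (raw_peak - 50):(raw_peak + 50)
  filt_peak <- win[1] + which.max(proc$ppg[win]) - 1
  expect_lte(abs(filt_peak - raw_peak), 1)
})

test_that("preprocess_signal validates inputs and returns aligned channels", {
  g <- generate_synthetic_ppg(synth_config(duration = 10))
  proc <- preprocess_signal(g$signal)
  expect_s3_class(proc, "processed_ppg")
  expect_length(proc$d1, length(proc$ppg))
  expect_length(proc$d3, length(proc$ppg))
  expect_true(all(is.finite(proc$ppg)))
  expect_length(proc$ppg_beat, round(length(proc$ppg) * 75 / 256))

  bad <- g$signal
  bad$samples[5] <- NA
  expect_error(preprocess_signal(bad), "non-finite")
})
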