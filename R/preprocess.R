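#' Filtering configuration for PPG preprocessing
#'
#' Bundles the preprocessing parameters: a zero-phase Chebyshev Type II
#' band-pass applied to the raw signal, a flat (boxcar) moving-average filter
#' (MAF) applied after it, a shorter MAF applied after each differentiation
#' stage, and the target rate of the resampled copy used by the beat detector.
#'
#' Defaults follow common practice for fingertip PPG: 0.5--12 Hz pass band
#' (the high-pass edge suppresses baseline wander while retaining content at
#' low heart rates; the low-pass edge avoids time-shifting of fiducial points
#' while removing high-frequency noise), a 50 ms signal MAF (~9 Hz cut-off),
#' a 10 ms derivative MAF (~45 Hz cut-off) and 75 Hz resampling for beat
#' detection.
#'
#' @param bp_low High-pass (lower stop-band) edge in Hz.
#' @param bp_high Low-pass (upper stop-band) edge in Hz.
#' @param bp_order Order of the one-way Chebyshev II prototype (the zero-phase
#'   forward-backward application squares the magnitude response).
#' @param bp_rs Stop-band attenuation of the prototype in dB.
#' @param maf_signal_ms Width of the signal MAF in ms.
#' @param maf_deriv_ms Width of the derivative MAF in ms.
#' @param resample_fs Sampling rate (Hz) of the resampled copy used for beat
#'   detection.
#' @return An object of class `"filter_config"`.
#' @export
filter_config <- function(bp_low = 0.5, bp_high = 12, bp_order = 4, bp_rs = 20,
                          maf_signal_ms = 50, maf_deriv_ms = 10,
                          resample_fs = 75) {
  stopifnot(bp_low > 0, bp_high > bp_low, bp_order >= 1,
            maf_signal_ms > 0, maf_deriv_ms > 0, resample_fs > 0)
  structure(list(bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 bp_rs = bp_rs, maf_signal_ms = maf_signal_ms,
                 maf_deriv_ms = maf_deriv_ms, resample_fs = resample_fs),
            class = "filter_config")
}

# The band-pass is realized as a cascade of a Chebyshev II high-pass and
# low-pass of the stated order: at high sampling rates the jointly designed
# band-pass transfer function is numerically unstable (its lower edge sits at
# ~1e-3 of Nyquist and coefficient rounding pushes poles outside the unit
# circle), while the cascaded sections remain stable.
bandpass_design <- function(fs, cfg) {
  list(hp = signal::cheby2(cfg$bp_order, cfg$bp_rs, cfg$bp_low / (fs / 2),
                           type = "high"),
       lp = signal::cheby2(cfg$bp_order, cfg$bp_rs, cfg$bp_high / (fs / 2),
                           type = "low"))
}

# Zero-phase IIR with odd-reflection padding to suppress edge transients.
# The high-pass poles decay with a time constant around a second, so the
# padding spans three seconds where the signal allows it.
filtfilt_padded <- function(filt, x, fs) {
  n <- length(x)
  npad <- min(n - 1L, max(round(3 * fs), 30L))
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase Chebyshev II band-pass filter
#'
#' Applies the designed band-pass forward and backward (zero phase: an in-band
#' sinusoid suffers no measurable phase shift). Edges are handled by
#' odd-reflection padding.
#'
#' @param x Numeric vector of raw PPG samples (or a signal list with `samples`
#'   and `fs`).
#' @param fs Sampling rate in Hz (ignored when `x` carries its own).
#' @param cfg A [filter_config()].
#' @return Filtered numeric vector, same length as the input.
#' @export
bandpass_filter <- function(x, fs = NULL, cfg = filter_config()) {
  if (is.list(x)) { fs <- x$fs; x <- x$samples }
  stopifnot(is.numeric(x), length(x) > 0, is.numeric(fs), fs > 0)
  if (fs <= 2 * cfg$bp_high)
    stop("sampling rate must exceed twice the upper band edge (",
         cfg$bp_high, " Hz)")
  if (length(x) < max(round(0.5 * fs), 6 * (2 * cfg$bp_order + 1)))
    stop("signal too short for the band-pass filter warm-up")
  des <- bandpass_design(fs, cfg)
  # removing the mean first keeps the residual DC leakage of the equiripple
  # stop band out of the output entirely
  filtfilt_padded(des$lp, filtfilt_padded(des$hp, x - mean(x), fs), fs)
}

#' Flat (boxcar) moving-average filter
#'
#' Centered boxcar of `width_ms`; the window length is rounded to samples and
#' forced odd so the kernel stays symmetric (zero phase). At the boundaries the
#' window shrinks, so the output has the same length as the input.
#'
#' @param x Numeric vector.
#' @param width_ms Window width in ms.
#' @param fs Sampling rate in Hz.
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, width_ms, fs) {
  stopifnot(width_ms > 0, fs > 0)
  w <- round(width_ms * fs / 1000)
  if (w %% 2 == 0) w <- w + 1
  if (w <= 1) {
    message("moving_average: window below one sample at fs = ", fs,
            " Hz; returning input unchanged")
    return(x)
  }
  h <- (w - 1L) / 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# first-order central difference scaled to units per second; one-sided at the
# ends. Central differences preserve extremum locations, which the fiducial
# definitions depend on.
central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d
}

#' Smoothed derivatives of the filtered PPG
#'
#' Computes the first three derivatives by successive central differencing,
#' with the short derivative MAF applied after each differentiation stage to
#' suppress amplified high-frequency noise.
#'
#' @param ppg Filtered PPG vector.
#' @param fs Sampling rate in Hz.
#' @param cfg A [filter_config()] (supplies the derivative MAF width).
#' @return List with elements `d1`, `d2`, `d3` (units: amplitude s^-1, s^-2,
#'   s^-3), each the same length as `ppg`.
#' @export
compute_derivatives <- function(ppg, fs, cfg = filter_config()) {
  d1 <- moving_average(central_diff(ppg, fs), cfg$maf_deriv_ms, fs)
  d2 <- moving_average(central_diff(d1, fs), cfg$maf_deriv_ms, fs)
  d3 <- moving_average(central_diff(d2, fs), cfg$maf_deriv_ms, fs)
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Fourier-method resampling
#'
#' Resamples a signal to a new rate via the FFT: the spectrum is truncated or
#' zero-padded and inverse-transformed, so band-limited content below the new
#' Nyquist rate is preserved exactly.
#'
#' @param x Numeric vector.
#' @param fs Original sampling rate in Hz.
#' @param target_fs Target sampling rate in Hz.
#' @return Vector of length `round(length(x) * target_fs / fs)`.
#' @export
resample_fourier <- function(x, fs, target_fs) {
  stopifnot(fs > 0, target_fs > 0)
  n <- length(x)
  m <- as.integer(round(n * target_fs / fs))
  if (m == n) return(x)
  X <- stats::fft(x)
  k <- min(m, n)
  h <- k %/% 2L
  Y <- complex(m)
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  nneg <- k - h - 1L
  if (nneg > 0L) Y[(m - nneg + 1L):m] <- X[(n - nneg + 1L):n]
  if (k %% 2L == 0L) {
    if (m < n) {
      Y[h + 1L] <- Y[h + 1L] + X[n - h + 1L]
    } else {
      Y[h + 1L] <- Y[h + 1L] * 0.5
      Y[m - h + 1L] <- Y[h + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Preprocess a raw PPG recording
#'
#' Runs the full preprocessing chain: band-pass filtering, signal MAF,
#' derivative computation with per-stage MAF smoothing, and Fourier resampling
#' of the filtered signal for beat detection. The first and last second are
#' treated as filter warm-up and excluded from downstream fiducial search.
#'
#' @param raw A raw signal as returned by [load_signal()] or
#'   [generate_synthetic_ppg()] (list with `samples` and `fs`), or a numeric
#'   vector combined with `fs`.
#' @param cfg A [filter_config()].
#' @param fs Sampling rate in Hz when `raw` is a bare numeric vector.
#' @return An object of class `"processed_ppg"`: filtered `ppg`, derivatives
#'   `d1`, `d2`, `d3`, the sampling rate `fs`, the resampled copy `ppg_beat`
#'   at `fs_beat` Hz, and the warm-up margin `warmup_s`.
#' @export
preprocess_signal <- function(raw, cfg = filter_config(), fs = NULL) {
  if (is.numeric(raw)) raw <- list(samples = raw, fs = fs)
  stopifnot(!is.null(raw$samples), !is.null(raw$fs))
  if (!all(is.finite(raw$samples))) stop("non-finite samples in input signal")
  ppg <- bandpass_filter(raw$samples, raw$fs, cfg)
  ppg <- moving_average(ppg, cfg$maf_signal_ms, raw$fs)
  der <- compute_derivatives(ppg, raw$fs, cfg)
  structure(list(ppg = ppg, d1 = der$d1, d2 = der$d2, d3 = der$d3,
                 fs = raw$fs,
                 ppg_beat = resample_fourier(ppg, raw$fs, cfg$resample_fs),
                 fs_beat = cfg$resample_fs,
                 warmup_s = 1),
            class = "processed_ppg")
}
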