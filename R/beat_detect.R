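#' Configuration for the adaptive systolic-peak detector
#'
#' The detector works on the low-rate (default 75 Hz) copy of the filtered
#' signal, in windows of `window_s` seconds. In each window the heart rate is
#' estimated from the dominant spectral content of an HR-band-filtered copy;
#' if the implied rate falls outside `[hr_min, hr_max]` the window is deemed
#' low quality and the previous window's rate is retained. Candidate peaks are
#' then taken from a peak-band-filtered copy whose upper cut-off adapts to the
#' window heart rate, thresholded by rank, and pruned with a refractory period
#' proportional to the HR-implied beat period.
#'
#' @param window_s Window length in s.
#' @param hr_min,hr_max Admissible heart-rate range in bpm.
#' @param iir_order Order of the zero-phase Chebyshev II prototypes used for
#'   the HR-estimation and peak-detection bands.
#' @param iir_rs Stop-band attenuation in dB.
#' @param refine_ms Half-width of the window (ms) used to refine detected
#'   peaks to the local maximum of the full-rate filtered PPG.
#' @param hr_band HR-estimation band in Hz.
#' @param peak_band_factor Upper peak-band edge as a multiple of the window
#'   heart rate (in Hz: `peak_band_factor * hr / 60`).
#' @param thresh_quantile Rank threshold: candidate maxima must exceed this
#'   quantile of the window's filtered amplitude.
#' @param refractory_frac Refractory period as a fraction of the HR-implied
#'   beat period (below 1 so HR underestimation does not drop true beats).
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(window_s = 10, hr_min = 30, hr_max = 200,
                            iir_order = 5, iir_rs = 20, refine_ms = 100,
                            hr_band = c(0.5, 3.3), peak_band_factor = 2.5,
                            thresh_quantile = 0.7, refractory_frac = 0.6) {
  stopifnot(window_s > 0, hr_min > 0, hr_min < hr_max)
  structure(list(window_s = window_s, hr_min = hr_min, hr_max = hr_max,
                 iir_order = iir_order, iir_rs = iir_rs,
                 refine_ms = refine_ms, hr_band = hr_band,
                 peak_band_factor = peak_band_factor,
                 thresh_quantile = thresh_quantile,
                 refractory_frac = refractory_frac),
            class = "detector_config")
}

# zero-phase band-pass used inside the detector; falls back to the raw segment
# when the segment is too short to filter
detector_bandpass <- function(x, fs, band, order, rs) {
  band[2L] <- min(band[2L], 0.95 * fs / 2)
  if (band[1L] >= band[2L] || length(x) < 6 * (2 * order + 1)) return(x - mean(x))
  flt <- signal::cheby2(order, rs, band / (fs / 2), type = "pass")
  filtfilt_padded(flt, x, fs)
}

#' Estimate the heart rate of one detector window
#'
#' The segment is filtered to the HR band and the dominant frequency of its
#' periodogram (searched over 0.3--5 Hz) gives the candidate rate. A candidate
#' outside `[hr_min, hr_max]`, or a degenerate (flat) segment, is rejected:
#' the previous window's rate (or the band midpoint when there is none) is
#' retained with `valid = FALSE`.
#'
#' @param segment Numeric vector at the beat-detection rate.
#' @param fs Sampling rate of `segment` in Hz.
#' @param prev_hr Previous window's heart rate in bpm, or `NULL`.
#' @param cfg A [detector_config()].
#' @return List with `hr` (bpm) and `valid` (logical).
#' @export
estimate_segment_hr <- function(segment, fs, prev_hr = NULL,
                                cfg = detector_config()) {
  fallback <- prev_hr %||% ((cfg$hr_min + cfg$hr_max) / 2)
  n <- length(segment)
  if (n < 2 * fs || stats::sd(segment) == 0)
    return(list(hr = fallback, valid = FALSE))
  # the candidate rate is the dominant periodogram frequency over a search
  # band deliberately wider than [hr_min, hr_max]/60, so that out-of-range
  # rhythms are identified at their true frequency and rejected rather than
  # aliased into the admissible band by pre-filtering
  y <- (segment - mean(segment)) *
    (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1)))
  nfft <- 2^ceiling(log2(8L * n))
  P <- Mod(stats::fft(c(y, numeric(nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  band <- which(freqs >= 0.3 & freqs <= 5)
  if (!length(band) || max(P[band]) <= 0)
    return(list(hr = fallback, valid = FALSE))
  cand_hr <- freqs[band][which.max(P[band])] * 60
  if (cand_hr < cfg$hr_min || cand_hr > cfg$hr_max)
    return(list(hr = fallback, valid = FALSE))
  list(hr = cand_hr, valid = TRUE)
}

#' Detect systolic peaks
#'
#' Windowed adaptive beat detection on the low-rate copy of the filtered PPG
#' (see [detector_config()]), followed by mapping of the detected indices to
#' the analysis rate and refinement to the local maximum of the full-rate
#' filtered PPG within `refine_ms`. Duplicate detections at window joins are
#' merged (the higher-amplitude peak is kept) and a global refractory of
#' `60 / hr_max` seconds is enforced.
#'
#' @param proc A `"processed_ppg"` from [preprocess_signal()].
#' @param cfg A [detector_config()].
#' @return An object of class `"beat_sequence"`: `sp_idx` (strictly increasing
#'   indices at the analysis rate), `sp_idx_beat` (indices at the detection
#'   rate), `segment_hr` (bpm per window) and `segment_valid`.
#' @export
detect_beats <- function(proc, cfg = detector_config()) {
  stopifnot(inherits(proc, "processed_ppg"))
  x <- proc$ppg_beat
  fs <- proc$fs_beat
  n <- length(x)
  wlen <- as.integer(round(cfg$window_s * fs))
  nwin <- max(1L, as.integer(ceiling(n / wlen)))
  ext <- as.integer(round(fs))  # 1 s context on each side of the window

  seg_hr <- numeric(nwin); seg_valid <- logical(nwin)
  prev_hr <- NULL
  peaks <- integer(0); peak_amp <- numeric(0)

  for (w in seq_len(nwin)) {
    ws <- (w - 1L) * wlen + 1L
    we <- min(w * wlen, n)
    est <- estimate_segment_hr(x[ws:we], fs, prev_hr, cfg)
    seg_hr[w] <- est$hr; seg_valid[w] <- est$valid
    prev_hr <- est$hr
    hr <- est$hr

    es <- max(1L, ws - ext); ee <- min(n, we + ext)
    seg <- x[es:ee]
    if (stats::sd(seg) == 0) next
    band <- c(0.5, max(1.5, cfg$peak_band_factor * hr / 60))
    y <- detector_bandpass(seg, fs, band, cfg$iir_order, cfg$iir_rs)
    cand <- local_extrema(y, "max")
    thr <- stats::quantile(y, cfg$thresh_quantile, names = FALSE)
    cand <- cand[y[cand] > thr]
    if (!length(cand)) next
    # refractory pruning, strongest candidates first
    refr <- as.integer(round(cfg$refractory_frac * 60 / hr * fs))
    keep <- integer(0)
    for (i in cand[order(-y[cand])]) {
      if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
    }
    keep <- sort(keep) + es - 1L
    inside <- keep >= ws & keep <= we
    peaks <- c(peaks, keep[inside])
    peak_amp <- c(peak_amp, x[keep[inside]])
  }

  if (length(peaks)) {
    o <- order(peaks); peaks <- peaks[o]; peak_amp <- peak_amp[o]
    # merge duplicates at window joins, then enforce the global refractory
    min_gap <- as.integer(round(60 / cfg$hr_max * fs))
    gap <- max(ms_to_samples(100, fs), min_gap)
    keep <- rep(TRUE, length(peaks))
    last <- 1L
    for (i in seq_along(peaks)[-1L]) {
      if (peaks[i] - peaks[last] < gap) {
        if (peak_amp[i] > peak_amp[last]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    peaks <- peaks[keep]
  }

  # map to the analysis rate and refine on the full-rate filtered PPG
  fs_an <- proc$fs
  half <- ms_to_samples(cfg$refine_ms, fs_an)
  sp <- integer(0)
  for (p in peaks) {
    i0 <- as.integer(round((p - 1) * fs_an / fs)) + 1L
    lo <- max(1L, i0 - half); hi <- min(length(proc$ppg), i0 + half)
    sp <- c(sp, lo + which.max(proc$ppg[lo:hi]) - 1L)
  }
  sp <- sort(unique(sp))
  if (length(sp) > 1L) {
    min_gap_an <- as.integer(round(60 / cfg$hr_max * fs_an))
    keep <- rep(TRUE, length(sp)); last <- 1L
    for (i in seq_along(sp)[-1L]) {
      if (sp[i] - sp[last] < min_gap_an) {
        if (proc$ppg[sp[i]] > proc$ppg[sp[last]]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    sp <- sp[keep]
  }

  structure(list(sp_idx = sp, sp_idx_beat = peaks,
                 segment_hr = seg_hr, segment_valid = seg_valid),
            class = "beat_sequence")
}
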