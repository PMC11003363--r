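#' Locate pulse onsets and offsets around detected systolic peaks
#'
#' For each systolic peak the candidate onset is the minimum of the filtered
#' PPG between the previous peak and the current one; it is then refined to
#' the first local maximum of the third derivative preceding the pulse's p1
#' point (the operational definition of the start of the systolic upslope --
#' typically, but not necessarily, a minimum). The offset of each pulse equals
#' the onset of the next, so retained pulses tile the record without overlap.
#' The last beat's offset is taken as the first local PPG minimum after its
#' peak; if none exists the beat is dropped.
#'
#' Because the onset definition needs per-pulse second/third-derivative points
#' that are themselves defined within the pulse, a provisional window (minimum
#' before the peak up to the next peak) is used to place provisional a, b and
#' p1 points, after which the onset is refined; fiducial detection then reruns
#' on the final window.
#'
#' Beats inside the filter warm-up margin at either end of the record are
#' discarded.
#'
#' @param proc A `"processed_ppg"` from [preprocess_signal()].
#' @param beats A `"beat_sequence"` from [detect_beats()].
#' @return Data frame with one row per pulse: `on`, `sp`, `off` (sample
#'   indices at the analysis rate) and `duration_ms`.
#' @export
detect_onsets_offsets <- function(proc, beats) {
  stopifnot(inherits(proc, "processed_ppg"))
  sp <- if (is.list(beats)) beats$sp_idx else beats
  fs <- proc$fs
  n <- length(proc$ppg)
  margin <- as.integer(round(proc$warmup_s * fs))
  sp <- sp[sp > margin & sp <= n - margin]
  if (length(sp) < 1L)
    return(data.frame(on = integer(0), sp = integer(0), off = integer(0),
                      duration_ms = numeric(0)))

  ibi <- if (length(sp) > 1L) stats::median(diff(sp)) else as.integer(round(fs))

  onset_for <- function(k) {
    lo <- if (k > 1L) sp[k - 1L] else max(1L, sp[k] - as.integer(round(1.2 * ibi)))
    seg <- lo:sp[k]
    on0 <- seg[which.min(proc$ppg[seg])]
    refine_onset(proc, on0, sp[k], ibi)
  }
  on <- vapply(seq_along(sp), onset_for, numeric(1))
  on <- as.integer(on)

  # surrogate offset for the final beat: the PPG minimum near the expected
  # next onset (one beat period ahead), refined like a regular onset when the
  # following upslope is still inside the record
  last_end <- {
    spN <- sp[length(sp)]
    expected <- on[length(on)] + as.integer(round(ibi))
    lo <- max(spN + 1L, expected - as.integer(round(0.35 * ibi)))
    hi <- min(n, expected + as.integer(round(0.15 * ibi)))
    if (hi - lo < 3L) NA_integer_
    else {
      seg <- lo:hi
      on0 <- seg[which.min(proc$ppg[seg])]
      pseudo_sp <- min(n - 1L, spN + as.integer(round(ibi)))
      if (pseudo_sp > on0 + 2L) refine_onset(proc, on0, pseudo_sp, ibi) else on0
    }
  }

  off <- c(on[-1L], last_end)
  keep <- !is.na(off) & on < sp & sp < off
  data.frame(on = on[keep], sp = sp[keep], off = off[keep],
             duration_ms = (off[keep] - on[keep]) / fs * 1000)
}

# refine a candidate onset to the first local maximum of PPG''' preceding the
# provisional p1 point; falls back to the candidate minimum when the
# derivative landmarks cannot be placed
refine_onset <- function(proc, on0, sp_i, ibi) {
  d2 <- proc$d2; d3 <- proc$d3
  seg_a <- on0:sp_i
  a_i <- seg_a[which.max(d2[seg_a])]
  hi_b <- min(length(d2), sp_i + as.integer(round(0.5 * ibi)))
  b_i <- first_in(local_extrema(d2[a_i:hi_b], "min") + a_i - 1L, a_i)
  if (is.na(b_i)) return(on0)
  hi_p1 <- min(length(d3), b_i + as.integer(round(0.6 * ibi)))
  p1_i <- first_in(local_extrema(d3[b_i:hi_p1], "max") + b_i - 1L, b_i)
  if (is.na(p1_i)) return(on0)
  lo <- max(1L, on0 - as.integer(round(0.2 * ibi)))
  cand <- last_in(local_extrema(d3[lo:p1_i], "max") + lo - 1L, lo, p1_i)
  if (is.na(cand)) on0 else cand
}
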