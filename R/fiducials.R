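#' Fiducial points of one pulse on the PPG derivatives
#'
#' Places the derivative fiducials within a pulse window `[on, off]`:
#' * `u` -- highest first-derivative amplitude between onset and systolic peak;
#'   `v` -- lowest first-derivative amplitude between `u` and `e`; `w` -- first
#'   first-derivative local maximum after `e` (following `v`) and before `f`.
#' * `a` -- highest second-derivative amplitude between onset and systolic
#'   peak; `b` -- first second-derivative local minimum after `a`; `c` --
#'   highest local maximum in `(b, e)` (else the inflection, a third-derivative
#'   zero-crossing); `d` -- lowest local minimum in `(c, e)` (else inflection);
#'   `e` -- highest local maximum after `b`, bounded by 60% of the pulse
#'   duration; `f` -- first local minimum after `e`, bounded by 80%.
#' * `p1` -- first third-derivative local maximum after `b`; `p2` -- last
#'   third-derivative local minimum between `b` and `d` (falling back to `d`
#'   when no admissible minimum exists).
#'
#' Undetectable points are returned as `NA`.
#'
#' @param proc A `"processed_ppg"`.
#' @param pulse List or one-row data frame with sample indices `on`, `sp`,
#'   `off`.
#' @return Named list of sample indices: `u`, `v`, `w`, `a`, `b`, `c`, `d`,
#'   `e`, `f`, `p1`, `p2`.
#' @export
detect_derivative_points <- function(proc, pulse) {
  on <- pulse$on; sp <- pulse$sp; off <- pulse$off
  stopifnot(on < sp, sp < off)
  d1 <- proc$d1; d2 <- proc$d2; d3 <- proc$d3
  dur <- off - on
  lim6 <- on + as.integer(round(0.6 * dur))
  lim8 <- on + as.integer(round(0.8 * dur))

  seg <- on:sp
  a <- seg[which.max(d2[seg])]
  if (d2[a] <= min(d2[seg])) a <- NA_integer_  # flat segment: no extrema

  b <- if (!is.na(a)) first_in(local_extrema(d2[a:off], "min") + a - 1L, a)
       else NA_integer_

  e <- NA_integer_
  if (!is.na(b) && lim6 > b) {
    cand <- local_extrema(d2[b:lim6], "max") + b - 1L
    cand <- cand[cand > b]
    if (length(cand)) e <- cand[which.max(d2[cand])]
  }

  # a candidate f must be followed by a rise of at least 2% of the pulse's
  # second-derivative range, so filter ripple in flat tails is not mistaken
  # for the post-e trough
  f <- NA_integer_
  if (!is.na(e) && lim8 > e) {
    cand <- local_extrema(d2[e:lim8], "min") + e - 1L
    cand <- cand[cand > e]
    s2 <- 0.02 * diff(range(d2[on:off]))
    for (ci in cand) {
      if (max(d2[ci:lim8]) - d2[ci] >= s2) { f <- ci; break }
    }
  }

  # inflection fallbacks exclude a 2% guard band around the bracketing
  # extrema, where the next-higher derivative is trivially zero
  guard <- function(lo, hi) max(1L, as.integer(ceiling(0.02 * (hi - lo))))
  cc <- NA_integer_
  if (!is.na(b) && !is.na(e) && e - b > 2L) {
    cand <- local_extrema(d2[b:e], "max") + b - 1L
    cand <- cand[cand > b & cand < e]
    if (length(cand)) cc <- cand[which.max(d2[cand])]
    else {
      z <- zero_crossing_idx(d3[b:e]) + b - 1L
      z <- z[z > b + guard(b, e) & z < e - guard(b, e)]
      if (length(z)) cc <- z[1L]
    }
  }

  d <- NA_integer_
  d_lo <- if (!is.na(cc)) cc else b
  if (!is.na(d_lo) && !is.na(e) && e - d_lo > 2L) {
    cand <- local_extrema(d2[d_lo:e], "min") + d_lo - 1L
    cand <- cand[cand > d_lo & cand < e]
    if (length(cand)) d <- cand[which.min(d2[cand])]
    else if (!is.na(cc)) {
      z <- zero_crossing_idx(d3[cc:e]) + cc - 1L
      z <- z[z > cc + guard(cc, e) & z < e - guard(cc, e)]
      if (length(z)) d <- z[length(z)]
    }
  }

  p1 <- if (!is.na(b))
    first_in(local_extrema(d3[b:off], "max") + b - 1L, b) else NA_integer_

  p2 <- NA_integer_
  if (!is.na(b) && !is.na(d) && d - b > 2L) {
    cand <- local_extrema(d3[b:d], "min") + b - 1L
    cand <- cand[cand > b & cand < d]
    p2 <- if (length(cand)) cand[length(cand)] else d
  } else if (!is.na(d)) p2 <- d

  seg_u <- on:sp
  u <- seg_u[which.max(d1[seg_u])]
  if (d1[u] <= min(d1[seg_u])) u <- NA_integer_

  v <- NA_integer_
  if (!is.na(u)) {
    v_hi <- if (!is.na(e)) e else lim8
    if (v_hi > u) {
      seg_v <- u:v_hi
      v <- seg_v[which.min(d1[seg_v])]
      if (d1[v] >= max(d1[seg_v])) v <- NA_integer_
    }
  }

  w <- NA_integer_
  if (!is.na(e)) {
    w_lo <- max(e, v, na.rm = TRUE)
    w_hi <- if (!is.na(f)) f else lim8
    if (w_hi > w_lo)
      w <- first_in(local_extrema(d1[w_lo:w_hi], "max") + w_lo - 1L, w_lo)
  }

  list(u = u, v = v, w = w, a = a, b = b, c = cc, d = d, e = e, f = f,
       p1 = p1, p2 = p2)
}

#' Dicrotic notch detection with morphology class
#'
#' Follows the fiducial definition: when a diastolic wave is present the notch
#' is the local PPG minimum preceding the (first) local maximum after the
#' systolic peak. When no such maximum exists, the notch is placed at the
#' zero-crossing of the second derivative between the `d` and `e` points (the
#' inflection on the downslope). The notch class records the morphology:
#' 1 incisura (true local minimum), 2 plateau (near-zero slope at the notch),
#' 3 gradient change only, 4 no discernible notch (`dn` absent).
#'
#' @param proc A `"processed_ppg"`.
#' @param pulse Pulse window (`on`, `sp`, `off`).
#' @param partial Derivative points from [detect_derivative_points()] (for the
#'   `d`/`e` fallback).
#' @return List with `dn` (sample index or `NA`) and `dn_class`.
#' @export
detect_dicrotic_notch <- function(proc, pulse, partial) {
  on <- pulse$on; sp <- pulse$sp; off <- pulse$off
  lim8 <- on + as.integer(round(0.8 * (off - on)))
  P <- proc$ppg

  amp_tol <- 0.02 * diff(range(P[on:off]))
  maxima <- local_extrema(P[sp:lim8], "max") + sp - 1L
  maxima <- maxima[maxima > sp]
  for (dp0 in maxima) {
    mins <- local_extrema(P[sp:dp0], "min") + sp - 1L
    mins <- mins[mins > sp & mins < dp0]
    if (!length(mins)) next
    dn <- mins[length(mins)]
    # the rebound must be material, not filter ripple
    if (P[dp0] - P[dn] < amp_tol) next
    cls <- if (plateau_at(proc, dn, on, off)) 2L else 1L
    return(list(dn = dn, dn_class = cls))
  }
  d <- partial$d; e <- partial$e
  if (!is.na(d) && !is.na(e) && e > d) {
    z <- zero_crossing_idx(proc$d2[d:e]) + d - 1L
    if (length(z)) return(list(dn = z[1L], dn_class = 3L))
  }
  list(dn = NA_integer_, dn_class = 4L)
}

# A plateau-class notch is a stretch of near-zero slope AND near-zero
# curvature around the notch: an incisura also has zero slope at its minimum
# but carries strong positive curvature there, so both conditions are needed
# to tell the classes apart.
plateau_at <- function(proc, idx, on, off) {
  w <- max(2L, as.integer(round(0.005 * proc$fs)))
  lo <- max(1L, idx - w); hi <- min(length(proc$d1), idx + w)
  all(abs(proc$d1[lo:hi]) < 0.02 * max(abs(proc$d1[on:off]))) &&
    abs(proc$d2[idx]) < 0.05 * max(abs(proc$d2[on:off]))
}

#' Diastolic peak detection
#'
#' The first local PPG maximum after the dicrotic notch and before 0.8 of the
#' pulse interval; when there is no maximum after the notch, the first local
#' maximum after the `e` point within the same bound. Absent if neither
#' window contains a local maximum.
#'
#' @param proc A `"processed_ppg"`.
#' @param pulse Pulse window (`on`, `sp`, `off`).
#' @param partial Detected points so far (uses `dn`, `e`).
#' @return Sample index of `dp`, or `NA`.
#' @export
detect_diastolic_peak <- function(proc, pulse, partial) {
  on <- pulse$on; off <- pulse$off
  lim8 <- on + as.integer(round(0.8 * (off - on)))
  P <- proc$ppg
  from <- if (!is.na(partial$dn)) partial$dn else partial$e
  if (is.na(from) || lim8 <= from) return(NA_integer_)
  amp_tol <- 0.02 * diff(range(P[on:pulse$off]))
  cand <- local_extrema(P[from:lim8], "max") + from - 1L
  cand <- cand[cand > from & cand < lim8]
  for (ci in cand) {
    if (P[ci] - min(P[from:ci]) >= amp_tol) return(ci)
  }
  NA_integer_
}

fiducial_point_names <- function() {
  c("on", "sp", "dn", "dp", "off", "u", "v", "w",
    "a", "b", "c", "d", "e", "f", "p1", "p2")
}

#' Detect the full fiducial set for each pulse
#'
#' Runs the derivative-point, dicrotic-notch and diastolic-peak detectors per
#' pulse, applies the optional correction pass, and flags pulses whose
#' systolic (onset to notch) or diastolic (notch to offset) durations fall
#' below the physiological minima of 120 ms and 300 ms.
#'
#' @param proc A `"processed_ppg"`.
#' @param pulses Data frame from [detect_onsets_offsets()].
#' @param correction Apply the consistency-correction pass (default `TRUE`).
#' @param min_sys_ms,min_dia_ms Duration floors used for the validity flag.
#' @return Data frame, one row per pulse: sample indices for all 16 fiducial
#'   points, `dn_class`, and `valid`.
#' @export
detect_fiducials <- function(proc, pulses, correction = TRUE,
                             min_sys_ms = 120, min_dia_ms = 300) {
  rows <- lapply(seq_len(nrow(pulses)), function(i) {
    p <- pulses[i, ]
    der <- detect_derivative_points(proc, p)
    dn <- detect_dicrotic_notch(proc, p, der)
    dp <- detect_diastolic_peak(proc, p, c(der, dn))
    data.frame(pulse = i, on = p$on, sp = p$sp, dn = dn$dn, dp = dp,
               off = p$off, u = der$u, v = der$v, w = der$w, a = der$a,
               b = der$b, c = der$c, d = der$d, e = der$e, f = der$f,
               p1 = der$p1, p2 = der$p2, dn_class = dn$dn_class)
  })
  fid <- do.call(rbind, rows)
  fid <- correct_fiducials(fid, proc = proc, enabled = correction)
  fs <- proc$fs
  tsys <- (fid$dn - fid$on) / fs * 1000
  tdia <- (fid$off - fid$dn) / fs * 1000
  fid$valid <- is.na(fid$dn) | (tsys >= min_sys_ms & tdia >= min_dia_ms)
  fid
}

#' Consistency correction of detected fiducial points
#'
#' Enforces the ordering invariants (`on <= u <= sp <= dn <= dp <= off`,
#' `a < b <= e < f`, `c`, `d` inside `(b, e)`, `p1`, `p2` inside the pulse).
#' A diastolic peak found at or before the notch is recomputed from the
#' updated notch (when the signal is available); points that remain
#' inconsistent are discarded rather than moved. With `enabled = FALSE` the
#' detections pass through unchanged. The pass is idempotent.
#'
#' @param fiducials Data frame of per-pulse fiducial indices.
#' @param proc Optional `"processed_ppg"` used to recompute the diastolic
#'   peak; without it an inconsistent `dp` is discarded.
#' @param enabled Apply corrections (default `TRUE`).
#' @return Corrected data frame of the same shape.
#' @export
correct_fiducials <- function(fiducials, proc = NULL, enabled = TRUE) {
  if (!enabled) return(fiducials)
  f <- fiducials
  bad <- function(x, lo, hi) !is.na(x) & (is.na(lo) | is.na(hi) | x < lo | x > hi)
  f$u[bad(f$u, f$on, f$sp)] <- NA_integer_
  f$a[bad(f$a, f$on, f$sp)] <- NA_integer_
  f$b[!is.na(f$b) & (is.na(f$a) | f$b <= f$a)] <- NA_integer_
  f$e[!is.na(f$e) & (is.na(f$b) | f$e < f$b)] <- NA_integer_
  f$f[!is.na(f$f) & (is.na(f$e) | f$f <= f$e)] <- NA_integer_
  f$c[!is.na(f$c) & (is.na(f$b) | is.na(f$e) | f$c <= f$b | f$c >= f$e)] <- NA_integer_
  f$d[!is.na(f$d) & (is.na(f$c) | is.na(f$e) | f$d < f$c | f$d >= f$e)] <- NA_integer_
  f$dn[bad(f$dn, f$sp, f$off)] <- NA_integer_

  redo <- !is.na(f$dp) & !is.na(f$dn) & f$dp <= f$dn
  if (any(redo) && !is.null(proc)) {
    for (i in which(redo)) {
      f$dp[i] <- detect_diastolic_peak(proc,
                                       list(on = f$on[i], sp = f$sp[i], off = f$off[i]),
                                       list(dn = f$dn[i], e = f$e[i]))
    }
    redo <- !is.na(f$dp) & !is.na(f$dn) & f$dp <= f$dn
  }
  f$dp[redo] <- NA_integer_
  f$dp[bad(f$dp, f$sp, f$off)] <- NA_integer_
  f$p1[bad(f$p1, f$on, f$off)] <- NA_integer_
  f$p2[bad(f$p2, f$on, f$off)] <- NA_integer_
  f
}
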