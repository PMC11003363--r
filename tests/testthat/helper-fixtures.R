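# Fixtures and independent oracles used across the suite. Everything here is
# written as plainly as possible (explicit loops, closed forms) so it stays an
# independent check on the package's vectorized implementations.

# Gaussian mixture and derivatives, re-derived from the closed forms.
gmix <- function(t, centers, amps, sigmas, order = 0) {
  out <- 0
  for (j in seq_along(centers)) {
    z <- t - centers[j]; s2 <- sigmas[j]^2
    g <- amps[j] * exp(-z^2 / (2 * s2))
    out <- out + switch(order + 1,
                        g,
                        -z / s2 * g,
                        (z^2 / s2^2 - 1 / s2) * g,
                        (3 * z / s2^2 - z^3 / s2^3) * g)
  }
  out
}

# A processed-signal stand-in whose derivative channels are the analytic
# derivatives (no filtering), for direct tests of the point-placement logic.
analytic_proc <- function(fs, dur_s, centers, amps, sigmas) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  structure(list(ppg = gmix(t, centers, amps, sigmas, 0),
                 d1 = gmix(t, centers, amps, sigmas, 1),
                 d2 = gmix(t, centers, amps, sigmas, 2),
                 d3 = gmix(t, centers, amps, sigmas, 3),
                 fs = fs, warmup_s = 0),
            class = "processed_ppg")
}

# Squared magnitude response of the zero-phase preprocessing band-pass,
# evaluated directly from the designed transfer functions.
bp_mag2 <- function(f, fs, cfg = filter_config()) {
  des <- pulsewave:::bandpass_design(fs, cfg)
  one <- function(flt) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
          sum(flt$a * z^(seq_along(flt$a) - 1)))^2
  }
  one(des$hp) * one(des$lp)
}

# Closed-form boxcar (moving average) magnitude at frequency f for an
# n-sample window.
boxcar_mag <- function(f, fs, n) {
  if (f == 0) return(1)
  abs(sin(pi * f * n / fs) / (n * sin(pi * f / fs)))
}

# ---- brute-force fiducial scanner -------------------------------------------
# Direct loop implementation of the point definitions on discrete sequences,
# with the same documented guards (0.6/0.8 duration bounds, 2% interior guard
# for inflection fallbacks, 2% prominence for f and the notch rebound).

bf_is_lmax <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(FALSE)
  if (x[i] <= x[i - 1]) return(FALSE)
  j <- i + 1
  while (j <= n && x[j] == x[i]) j <- j + 1
  j <= n && x[j] < x[i] && x[i - 1] < x[i]
}

bf_is_lmin <- function(x, i) bf_is_lmax(-x, i)

bf_lmax_in <- function(x, lo, hi) {
  out <- integer(0)
  for (i in seq(max(lo, 2), min(hi, length(x) - 1)))
    if (bf_is_lmax(x, i)) out <- c(out, i)
  out
}
bf_lmin_in <- function(x, lo, hi) bf_lmax_in(-x, lo, hi)

bf_zc_in <- function(x, lo, hi) {
  out <- integer(0)
  for (i in seq(lo, hi - 1)) {
    if (x[i] == 0) out <- c(out, i)
    else if (sign(x[i]) * sign(x[i + 1]) < 0) {
      frac <- x[i] / (x[i] - x[i + 1])
      out <- c(out, if (frac < 0.5) i else i + 1)
    }
  }
  unique(out)
}

bf_fiducials <- function(proc, on, sp, off) {
  d1 <- proc$d1; d2 <- proc$d2; d3 <- proc$d3; P <- proc$ppg
  dur <- off - on
  lim6 <- on + round(0.6 * dur)
  lim8 <- on + round(0.8 * dur)
  pick_max <- function(series, lo, hi) {
    seg <- series[lo:hi]
    i <- lo + which.max(seg) - 1
    if (series[i] <= min(seg)) NA_integer_ else i
  }
  a <- pick_max(d2, on, sp)
  b <- NA_integer_
  if (!is.na(a)) {
    cand <- bf_lmin_in(d2, a + 1, off)
    if (length(cand)) b <- cand[1]
  }
  e <- NA_integer_
  if (!is.na(b) && lim6 > b) {
    cand <- bf_lmax_in(d2, b + 1, lim6)
    if (length(cand)) e <- cand[which.max(d2[cand])]
  }
  f <- NA_integer_
  if (!is.na(e) && lim8 > e) {
    s2 <- 0.02 * (max(d2[on:off]) - min(d2[on:off]))
    for (ci in bf_lmin_in(d2, e + 1, lim8)) {
      if (max(d2[ci:lim8]) - d2[ci] >= s2) { f <- ci; break }
    }
  }
  cc <- NA_integer_
  if (!is.na(b) && !is.na(e) && e - b > 2) {
    cand <- bf_lmax_in(d2, b + 1, e - 1)
    if (length(cand)) cc <- cand[which.max(d2[cand])]
    else {
      gd <- max(1, ceiling(0.02 * (e - b)))
      z <- bf_zc_in(d3, b, e)
      z <- z[z > b + gd & z < e - gd]
      if (length(z)) cc <- z[1]
    }
  }
  d <- NA_integer_
  dlo <- if (!is.na(cc)) cc else b
  if (!is.na(dlo) && !is.na(e) && e - dlo > 2) {
    cand <- bf_lmin_in(d2, dlo + 1, e - 1)
    if (length(cand)) d <- cand[which.min(d2[cand])]
    else if (!is.na(cc)) {
      gd <- max(1, ceiling(0.02 * (e - cc)))
      z <- bf_zc_in(d3, cc, e)
      z <- z[z > cc + gd & z < e - gd]
      if (length(z)) d <- z[length(z)]
    }
  }
  p1 <- NA_integer_
  if (!is.na(b)) {
    cand <- bf_lmax_in(d3, b + 1, off)
    if (length(cand)) p1 <- cand[1]
  }
  p2 <- NA_integer_
  if (!is.na(b) && !is.na(d)) {
    cand <- if (d - b > 2) bf_lmin_in(d3, b + 1, d - 1) else integer(0)
    p2 <- if (length(cand)) cand[length(cand)] else d
  }
  u <- pick_max(d1, on, sp)
  v <- NA_integer_
  if (!is.na(u)) {
    vh <- if (!is.na(e)) e else lim8
    if (vh > u) {
      seg <- d1[u:vh]
      i <- u + which.min(seg) - 1
      if (d1[i] < max(seg)) v <- i
    }
  }
  w <- NA_integer_
  if (!is.na(e)) {
    wl <- max(e, v, na.rm = TRUE)
    wh <- if (!is.na(f)) f else lim8
    if (wh > wl) {
      cand <- bf_lmax_in(d1, wl + 1, wh)
      if (length(cand)) w <- cand[1]
    }
  }
  # dicrotic notch / diastolic peak
  dn <- NA_integer_; dp <- NA_integer_; cls <- 4L
  amp_tol <- 0.02 * (max(P[on:off]) - min(P[on:off]))
  for (m in bf_lmax_in(P, sp + 1, lim8)) {
    mins <- bf_lmin_in(P, sp + 1, m - 1)
    if (!length(mins)) next
    cand <- mins[length(mins)]
    if (P[m] - P[cand] < amp_tol) next
    dn <- cand
    sl <- max(abs(d1[on:off]))
    lo2 <- max(1, dn - 2); hi2 <- min(length(d1), dn + 2)
    cls <- if (all(abs(d1[lo2:hi2]) < 0.02 * sl)) 2L else 1L
    break
  }
  if (is.na(dn) && !is.na(d) && !is.na(e) && e > d) {
    z <- bf_zc_in(d2, d, e)
    if (length(z)) { dn <- z[1]; cls <- 3L }
  }
  from <- if (!is.na(dn)) dn else e
  if (!is.na(from) && lim8 > from) {
    for (m in bf_lmax_in(P, from + 1, lim8 - 1)) {
      if (P[m] - min(P[from:m]) >= amp_tol) { dp <- m; break }
    }
  }
  list(on = on, sp = sp, dn = dn, dp = dp, off = off, u = u, v = v, w = w,
       a = a, b = b, c = cc, d = d, e = e, f = f, p1 = p1, p2 = p2,
       dn_class = cls)
}

# ---- file-format fixture writers (binary fixtures built at test time) -------

write_mat4 <- function(path, vars) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(vars)) {
    v <- as.numeric(vars[[nm]])
    writeBin(as.integer(c(0L, length(v), 1L, 0L, nchar(nm) + 1L)), con,
             size = 4, endian = "little")
    writeBin(charToRaw(nm), con)
    writeBin(as.raw(0L), con)
    writeBin(v, con, size = 8, endian = "little")
  }
  invisible(path)
}

write_edf <- function(path, channels, fs, record_s = 1) {
  # channels: named list of equal-length numeric vectors
  ns <- length(channels)
  n <- length(channels[[1]])
  ndr <- as.integer(n / (fs * record_s))
  spr <- as.integer(fs * record_s)
  pad <- function(s, w) substr(formatC(s, width = w, flag = "-"), 1, w)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256 * (1 + ns)), 8); wr("", 44)
  wr(as.character(ndr), 8); wr(as.character(record_s), 8)
  wr(as.character(ns), 4)
  for (nm in names(channels)) wr(nm, 16)
  for (i in seq_len(ns)) wr("transducer", 80)
  for (i in seq_len(ns)) wr("au", 8)
  phys_min <- vapply(channels, min, numeric(1))
  phys_max <- vapply(channels, max, numeric(1))
  phys_max <- ifelse(phys_max == phys_min, phys_min + 1, phys_max)
  for (i in seq_len(ns)) wr(as.character(signif(phys_min[i], 6)), 8)
  for (i in seq_len(ns)) wr(as.character(signif(phys_max[i], 6)), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(spr), 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- lapply(seq_len(ns), function(i) {
    x <- channels[[i]]
    as.integer(round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 -
                       32768))
  })
  for (r in seq_len(ndr)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns))
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

# morphology grid shared by the fiducial-accuracy checks: the spec ranges for
# systolic width and diastolic amplitude, plus two reflection-wave cells that
# exercise the c/d/p2 substructure
morphology_grid <- function() {
  g <- expand.grid(sys_sigma = c(0.05, 0.10, 0.15),
                   dia_amp = c(0, 0.3, 0.6))
  g$dia_mu <- 0.62; g$dia_sigma <- 0.12
  g$ref_amp <- 0; g$ref_mu <- 0.45; g$ref_sigma <- 0.09
  extra <- data.frame(sys_sigma = c(0.12, 0.13), dia_amp = c(0.5, 0.5),
                      dia_mu = c(0.62, 0.63), dia_sigma = c(0.05, 0.06),
                      ref_amp = c(0.5, 0.5), ref_mu = c(0.45, 0.45),
                      ref_sigma = c(0.08, 0.08))
  rbind(g, extra)
}

# pooled detection-vs-truth errors over the grid (ms), one element per point
grid_fiducial_errors <- function(fs = 500, duration = 20, hr = 60) {
  pts <- c("on", "sp", "dn", "dp", "off", "u", "v", "w",
           "a", "b", "c", "d", "e", "f", "p1", "p2")
  errs <- stats::setNames(lapply(pts, function(p) numeric(0)), pts)
  grid <- morphology_grid()
  for (k in seq_len(nrow(grid))) {
    cfg <- synth_config(hr = hr, duration = duration, fs = fs,
                        sys_sigma = grid$sys_sigma[k],
                        dia_amp = grid$dia_amp[k], dia_mu = grid$dia_mu[k],
                        dia_sigma = grid$dia_sigma[k],
                        ref_amp = grid$ref_amp[k], ref_mu = grid$ref_mu[k],
                        ref_sigma = grid$ref_sigma[k])
    g <- generate_synthetic_ppg(cfg)
    res <- ppg_pipeline(g$signal)
    fid <- res$fiducials
    gt <- g$ground_truth
    det_sp_ms <- (fid$sp - 1) / res$fs * 1000
    m <- vapply(det_sp_ms, function(s) which.min(abs(gt$sp - s)), integer(1))
    for (p in pts) {
      e <- (fid[[p]] - 1) / res$fs * 1000 - gt[[p]][m]
      errs[[p]] <- c(errs[[p]], e[!is.na(e)])
    }
  }
  errs
}
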