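#' Configuration for the synthetic PPG generator
#'
#' Each beat is modelled as the sum of a systolic and a diastolic Gaussian
#' wave on the beat's period grid; beats are concatenated, and baseline wander
#' (a slow sinusoid) and white noise at a given SNR can be added. Wave
#' positions and widths are expressed as fractions of the beat period so the
#' morphology is heart-rate invariant.
#'
#' The two-Gaussian model is used because all of its derivatives are available
#' in closed form, so every fiducial point of the noise-free continuous model
#' can be located exactly by root-finding and serves as ground truth for the
#' discrete detectors. It emulates a fingertip transmission-mode pulse shape
#' (sharp systolic wave, smaller reflected diastolic wave); it is not a
#' physiological simulator.
#'
#' @param hr Heart rate in bpm (30--200).
#' @param duration Recording length in s.
#' @param fs Sampling rate in Hz.
#' @param sys_amp,sys_mu,sys_sigma Systolic wave amplitude (a.u.), centre and
#'   width (fractions of the beat period).
#' @param dia_amp,dia_mu,dia_sigma Diastolic wave parameters; `dia_amp = 0`
#'   removes the diastolic wave (class-4 notch morphology).
#' @param ref_amp,ref_mu,ref_sigma Optional late-systolic reflection wave
#'   (default off). A moderate reflection wave between the systolic and
#'   diastolic waves produces the c--d substructure of the second derivative
#'   seen in pulse waves with pronounced wave reflection.
#' @param baseline_amp,baseline_freq Amplitude (a.u.) and frequency (Hz) of
#'   sinusoidal baseline wander.
#' @param noise_snr_db Additive white-noise level as SNR in dB relative to the
#'   clean pulse component; `Inf` disables noise.
#' @param hr_jitter_pct Standard deviation of per-beat period jitter, percent.
#' @param seed Optional RNG seed; identical seeds give identical output.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(hr = 60, duration = 60, fs = 256,
                         sys_amp = 1, sys_mu = 0.30, sys_sigma = 0.10,
                         dia_amp = 0.35, dia_mu = 0.62, dia_sigma = 0.12,
                         ref_amp = 0, ref_mu = 0.45, ref_sigma = 0.09,
                         baseline_amp = 0, baseline_freq = 0.25,
                         noise_snr_db = Inf, hr_jitter_pct = 0, seed = NULL) {
  stopifnot(hr >= 30, hr <= 200, duration > 0, fs > 0,
            sys_amp >= 0, dia_amp >= 0, ref_amp >= 0,
            sys_sigma > 0, dia_sigma > 0, ref_sigma > 0,
            dia_mu > sys_mu)
  if (ref_amp > 0) stopifnot(ref_mu > sys_mu, ref_mu < dia_mu)
  structure(list(hr = hr, duration = duration, fs = fs,
                 sys_amp = sys_amp, sys_mu = sys_mu, sys_sigma = sys_sigma,
                 dia_amp = dia_amp, dia_mu = dia_mu, dia_sigma = dia_sigma,
                 ref_amp = ref_amp, ref_mu = ref_mu, ref_sigma = ref_sigma,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 noise_snr_db = noise_snr_db, hr_jitter_pct = hr_jitter_pct,
                 seed = seed),
            class = "synth_config")
}

# Gaussian mixture and its first three analytic derivatives.
gauss_mix <- function(t, centers, amps, sigmas, order = 0L) {
  out <- numeric(length(t))
  for (j in seq_along(centers)) {
    if (amps[j] == 0) next
    z <- t - centers[j]
    s2 <- sigmas[j]^2
    g <- amps[j] * exp(-z^2 / (2 * s2))
    out <- out + switch(order + 1L,
      g,
      -z / s2 * g,
      (z^2 / s2^2 - 1 / s2) * g,
      (3 * z / s2^2 - z^3 / s2^3) * g)
  }
  out
}

# --- continuous-domain search utilities (grid scan + local refinement) -------

cont_extrema <- function(fun, lo, hi, type = c("max", "min"), n_grid = 1200L) {
  type <- match.arg(type)
  if (hi <= lo) return(numeric(0))
  tt <- seq(lo, hi, length.out = n_grid)
  y <- fun(tt)
  idx <- local_extrema(if (type == "min") -y else y, "max")
  vapply(idx, function(i) {
    o <- stats::optimize(fun,
                         lower = tt[max(1L, i - 1L)],
                         upper = tt[min(n_grid, i + 1L)],
                         maximum = (type == "max"),
                         tol = 1e-9)
    if (type == "max") o$maximum else o$minimum
  }, numeric(1))
}

cont_argext <- function(fun, lo, hi, type = c("max", "min")) {
  type <- match.arg(type)
  cand <- c(cont_extrema(fun, lo, hi, type), lo, hi)
  v <- fun(cand)
  cand[if (type == "max") which.max(v) else which.min(v)]
}

cont_zeros <- function(fun, lo, hi, n_grid = 1200L) {
  if (hi <= lo) return(numeric(0))
  tt <- seq(lo, hi, length.out = n_grid)
  y <- fun(tt)
  i <- which(sign(y[-n_grid]) * sign(y[-1L]) < 0)
  vapply(i, function(j)
    stats::uniroot(fun, lower = tt[j], upper = tt[j + 1L], tol = 1e-9)$root,
    numeric(1))
}

first_after <- function(v, a, b = Inf) {
  v <- v[v > a & v <= b]
  if (length(v)) min(v) else NA_real_
}
last_before <- function(v, a, b) {
  v <- v[v >= a & v < b]
  if (length(v)) max(v) else NA_real_
}

# Ground-truth fiducials for one beat of the continuous model, applying the
# same operational definitions used by the discrete detector, but by
# root-finding on the closed-form derivatives. All times in seconds.
beat_truth <- function(i, starts, periods, centers, amps, sigmas) {
  nb <- length(starts)
  use <- which(abs(starts - starts[i]) < 2.5 * max(periods))
  jj <- sort(unique(c(outer(use, c(0L, nb, 2L * nb), `+`))))  # sys+dia+ref
  jj <- jj[jj >= 1 & jj <= 3 * nb]
  f <- function(ord) function(t) gauss_mix(t, centers[jj], amps[jj], sigmas[jj], ord)
  f0 <- f(0L); f1 <- f(1L); f2 <- f(2L); f3 <- f(3L)

  b0 <- starts[i]; Ti <- periods[i]
  sp <- cont_argext(f0, b0, b0 + Ti, "max")
  sp_prev <- if (i > 1L) cont_argext(f0, starts[i - 1L], b0, "max")
             else b0 - 0.7 * Ti
  w0 <- cont_argext(f0, sp_prev, sp, "min")           # provisional foot
  a_t <- cont_argext(f2, w0, sp, "max")
  b_t <- first_after(cont_extrema(f2, a_t, sp + 0.5 * Ti, "min"), a_t)
  p1 <- if (is.na(b_t)) NA_real_ else
    first_after(cont_extrema(f3, b_t, b_t + 0.6 * Ti, "max"), b_t)
  on <- if (is.na(p1)) w0 else {
    cand <- last_before(cont_extrema(f3, w0 - 0.2 * Ti, p1, "max"),
                        w0 - 0.2 * Ti, p1 - 1e-9)
    if (is.na(cand)) w0 else cand
  }
  list(on = on, sp = sp, foot = w0, a = a_t, b = b_t, p1 = p1,
       f0 = f0, f1 = f1, f2 = f2, f3 = f3, Ti = Ti)
}

# Completes the per-beat truth once the next beat's onset (= offset) is known.
finish_truth <- function(tr, off) {
  f0 <- tr$f0; f1 <- tr$f1; f2 <- tr$f2; f3 <- tr$f3
  on <- tr$on; sp <- tr$sp; a_t <- tr$a; b_t <- tr$b; p1 <- tr$p1
  Tpi <- off - on
  lim6 <- on + 0.6 * Tpi
  lim8 <- on + 0.8 * Tpi
  grid <- seq(on, off, length.out = 800L)
  rng2 <- diff(range(f2(grid)))
  e_cand <- cont_extrema(f2, b_t, lim6, "max")
  e_t <- if (length(e_cand)) e_cand[which.max(f2(e_cand))] else NA_real_
  # mirror the detector's prominence guard: a candidate f must be followed by
  # a material rise, rejecting numerically flat tail extrema
  f_t <- NA_real_
  if (!is.na(e_t)) {
    for (cand in sort(cont_extrema(f2, e_t, lim8, "min"))) {
      if (cand <= e_t) next
      tail_grid <- seq(cand, lim8, length.out = 200L)
      if (max(f2(tail_grid)) - f2(cand) >= 0.02 * rng2) { f_t <- cand; break }
    }
  }
  # inflection fallbacks exclude a 2% guard band around the bracketing
  # extrema, where the next-higher derivative is trivially zero
  c_cand <- if (!is.na(e_t)) cont_extrema(f2, b_t, e_t, "max") else numeric(0)
  c_cand <- c_cand[c_cand > b_t + 1e-9 & c_cand < e_t - 1e-9]
  c_t <- if (length(c_cand)) c_cand[which.max(f2(c_cand))] else {
    z <- if (!is.na(e_t)) cont_zeros(f3, b_t, e_t) else numeric(0)
    z <- z[z > b_t + 0.02 * (e_t - b_t) & z < e_t - 0.02 * (e_t - b_t)]
    if (length(z)) z[1L] else NA_real_
  }
  d_lo <- if (!is.na(c_t)) c_t else b_t
  d_cand <- if (!is.na(e_t)) cont_extrema(f2, d_lo, e_t, "min") else numeric(0)
  d_cand <- d_cand[d_cand > d_lo + 1e-9 & d_cand < e_t - 1e-9]
  d_t <- if (length(d_cand)) d_cand[which.min(f2(d_cand))] else {
    z <- if (!is.na(c_t) && !is.na(e_t)) cont_zeros(f3, c_t, e_t) else numeric(0)
    z <- z[z > c_t + 0.02 * (e_t - c_t) & z < e_t - 0.02 * (e_t - c_t)]
    if (length(z)) z[length(z)] else NA_real_
  }
  p2_cand <- if (!is.na(d_t)) cont_extrema(f3, b_t, d_t, "min") else numeric(0)
  p2 <- if (length(p2_cand)) p2_cand[length(p2_cand)] else d_t
  u_t <- cont_argext(f1, on, sp, "max")
  v_hi <- if (!is.na(e_t)) e_t else lim8
  v_t <- cont_argext(f1, u_t, v_hi, "min")
  w_lo <- max(v_t, e_t, na.rm = TRUE)
  w_hi <- if (!is.na(f_t)) f_t else lim8
  w_t <- first_after(cont_extrema(f1, w_lo, w_hi, "max"), w_lo)

  # dicrotic notch / diastolic peak on the continuous pulse; the diastolic
  # rebound must exceed 2% of the pulse amplitude range (detector's guard)
  amp_tol <- 0.02 * diff(range(f0(grid)))
  dp <- NA_real_; dn <- NA_real_; dn_class <- NA_integer_
  dp_cand <- sort(cont_extrema(f0, sp, lim8, "max"))
  dp_cand <- dp_cand[dp_cand > sp + 1e-9]
  for (cand in dp_cand) {
    mins <- cont_extrema(f0, sp, cand, "min")
    mins <- mins[mins > sp + 1e-9 & mins < cand - 1e-9]
    if (!length(mins)) next
    if (f0(cand) - f0(mins[length(mins)]) < amp_tol) next
    dp <- cand; dn <- mins[length(mins)]; dn_class <- 1L
    break
  }
  if (is.na(dp)) {
    dp <- NA_real_
    z <- if (!is.na(d_t) && !is.na(e_t)) cont_zeros(f2, d_t, e_t) else numeric(0)
    dn <- if (length(z)) z[1L] else NA_real_
    dn_class <- if (is.na(dn)) 4L else 3L
  }
  list(on = on, sp = sp, dn = dn, dp = dp, off = off,
       u = u_t, v = v_t, w = w_t,
       a = a_t, b = b_t, c = c_t, d = d_t, e = e_t, f = f_t,
       p1 = p1, p2 = p2, dn_class = dn_class, foot = tr$foot)
}

#' Generate a synthetic PPG recording with analytic ground truth
#'
#' Builds the two-Gaussian beat train described in [synth_config()], adds the
#' optional baseline sinusoid and white noise, and derives per-beat
#' ground-truth fiducial times from the noise-free continuous model by
#' bracketed root-finding on its closed-form derivatives. The same seed always
#' yields bitwise-identical output.
#'
#' @param cfg A [synth_config()].
#' @return List with `signal` (list: `samples`, `fs`, `start_time`, `source`)
#'   and `ground_truth`, a data frame with one row per beat giving fiducial
#'   times in ms from signal start (`on`, `sp`, `dn`, `dp`, `off`, `u`, `v`,
#'   `w`, `a`--`f`, `p1`, `p2`), the waveform-foot time `foot`, and the
#'   dicrotic-notch class `dn_class` (1 incisura, 3 gradient change, 4 absent).
#'   The last beat has no offset (no following onset) and is dropped from the
#'   ground truth.
#' @export
generate_synthetic_ppg <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  T0 <- 60 / cfg$hr

  starts <- numeric(0); periods <- numeric(0); t0 <- 0
  while (t0 < cfg$duration) {
    jit <- if (cfg$hr_jitter_pct > 0)
      clamp(stats::rnorm(1, 0, cfg$hr_jitter_pct / 100), -0.3, 0.3) else 0
    Ti <- T0 * (1 + jit)
    starts <- c(starts, t0); periods <- c(periods, Ti)
    t0 <- t0 + Ti
  }
  nb <- length(starts)

  centers <- c(starts + cfg$sys_mu * periods, starts + cfg$dia_mu * periods,
               starts + cfg$ref_mu * periods)
  amps <- c(rep(cfg$sys_amp, nb), rep(cfg$dia_amp, nb), rep(cfg$ref_amp, nb))
  sigmas <- c(cfg$sys_sigma * periods, cfg$dia_sigma * periods,
              cfg$ref_sigma * periods)

  n <- as.integer(round(cfg$duration * cfg$fs))
  tt <- (seq_len(n) - 1) / cfg$fs
  clean <- gauss_mix(tt, centers, amps, sigmas, 0L)
  samples <- clean +
    cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq * tt)
  if (is.finite(cfg$noise_snr_db)) {
    sd_n <- sqrt(stats::var(clean) / 10^(cfg$noise_snr_db / 10))
    samples <- samples + stats::rnorm(n, 0, sd_n)
  }

  # ground truth: with no jitter all interior beats are congruent, so compute
  # one interior beat and translate; otherwise compute each beat.
  uniform <- cfg$hr_jitter_pct == 0
  truth_of <- function(i) beat_truth(i, starts, periods, centers, amps, sigmas)
  # the final beat has no following onset: only the points that do not need
  # the pulse offset are reported for it
  partial_row <- function(tr)
    list(on = tr$on, sp = tr$sp, dn = NA_real_, dp = NA_real_, off = NA_real_,
         u = NA_real_, v = NA_real_, w = NA_real_, a = tr$a, b = tr$b,
         c = NA_real_, d = NA_real_, e = NA_real_, f = NA_real_,
         p1 = tr$p1, p2 = NA_real_, dn_class = NA_integer_, foot = tr$foot)
  rows <- vector("list", nb)
  if (uniform && nb >= 4L) {
    ref <- 3L
    tr_ref <- truth_of(ref)
    fin_ref <- finish_truth(tr_ref, tr_ref$on + T0)
    for (i in seq_len(nb - 1L)) {
      shift <- starts[i] - starts[ref]
      r <- lapply(fin_ref[setdiff(names(fin_ref), "dn_class")],
                  function(v) v + shift)
      r$dn_class <- fin_ref$dn_class
      rows[[i]] <- r
    }
    # first beat: no preceding beat, recompute honestly
    rows[[1L]] <- finish_truth(truth_of(1L), rows[[2L]]$on)
    rows[[nb]] <- partial_row(truth_of(nb))
  } else {
    trs <- lapply(seq_len(nb), truth_of)
    for (i in seq_len(nb - 1L)) rows[[i]] <- finish_truth(trs[[i]], trs[[i + 1L]]$on)
    rows[[nb]] <- partial_row(trs[[nb]])
  }
  gt <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(beat = i,
               on = r$on, sp = r$sp, dn = r$dn %||% NA_real_,
               dp = r$dp %||% NA_real_, off = r$off %||% NA_real_,
               u = r$u, v = r$v, w = r$w, a = r$a, b = r$b, c = r$c,
               d = r$d, e = r$e, f = r$f, p1 = r$p1, p2 = r$p2,
               foot = r$foot, dn_class = r$dn_class)
  }))
  tcols <- setdiff(names(gt), c("beat", "dn_class"))
  gt[tcols] <- lapply(gt[tcols], function(v) v * 1000)  # seconds -> ms
  # beats whose truth spills outside the recording are not usable
  gt <- gt[gt$on >= 0 &
             (is.na(gt$off) | gt$off <= cfg$duration * 1000), , drop = FALSE]

  list(signal = list(samples = samples, fs = cfg$fs, start_time = 0,
                     source = "synthetic two-Gaussian PPG"),
       ground_truth = gt)
}
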