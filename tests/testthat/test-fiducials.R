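# Analytic single-pulse cases: a Gaussian's derivative extrema have closed
# forms (first derivative at mu +/- sigma, second derivative max at
# mu - sqrt(3) sigma with the first following minimum at mu), so the point
# placement can be checked to one sample on unfiltered analytic channels.
test_that("derivative points land on the analytic Gaussian extrema", {
  fs <- 1000
  proc <- analytic_proc(fs, 0.8, centers = 0.4, amps = 1, sigmas = 0.08)
  pulse <- list(on = 1L, sp = which.max(proc$ppg), off = length(proc$ppg))
  pts <- detect_derivative_points(proc, pulse)
  ms <- function(i) (i - 1) / fs * 1000
  expect_equal(ms(pts$u), 320, tolerance = 2)            # mu - sigma
  expect_equal(ms(pts$v), 480, tolerance = 2)            # mu + sigma
  expect_equal(ms(pts$a), 400 - sqrt(3) * 80, tolerance = 2)
  expect_equal(ms(pts$b), 400, tolerance = 2)            # first d2 minimum
  expect_equal(ms(pts$p1), 400 + 0.7420 * 80, tolerance = 2)  # d3 maximum
})

test_that("a flat pulse has no detectable derivative points", {
  proc <- structure(list(ppg = rep(1, 500), d1 = rep(0, 500),
                         d2 = rep(0, 500), d3 = rep(0, 500), fs = 500,
                         warmup_s = 0),
                    class = "processed_ppg")
  pts <- detect_derivative_points(proc, list(on = 10L, sp = 250L, off = 490L))
  expect_true(all(is.na(unlist(pts))))
  dn <- detect_dicrotic_notch(proc, list(on = 10L, sp = 250L, off = 490L), pts)
  expect_true(is.na(dn$dn))
  expect_equal(dn$dn_class, 4L)
})

test_that("a clear diastolic wave gives a class-1 notch at the inter-wave
           minimum and a diastolic peak at the second wave", {
  fs <- 1000
  # systolic wave at 300 ms, diastolic wave (0.4 amplitude) at 600 ms
  proc <- analytic_proc(fs, 1, centers = c(0.3, 0.6), amps = c(1, 0.4),
                        sigmas = c(0.08, 0.09))
  pulse <- list(on = 1L, sp = which.max(proc$ppg), off = 1000L)
  pts <- detect_derivative_points(proc, pulse)
  dn <- detect_dicrotic_notch(proc, pulse, pts)
  expect_equal(dn$dn_class, 1L)
  # numeric minimization oracle on the continuous model
  true_min <- stats::optimize(function(t)
    gmix(t, c(0.3, 0.6), c(1, 0.4), c(0.08, 0.09)),
    lower = 0.35, upper = 0.55)$minimum * 1000
  expect_lt(abs((dn$dn - 1) / fs * 1000 - true_min), 10)
  dp <- detect_diastolic_peak(proc, pulse, c(pts, dn))
  true_max <- stats::optimize(function(t)
    gmix(t, c(0.3, 0.6), c(1, 0.4), c(0.08, 0.09)),
    lower = 0.5, upper = 0.7, maximum = TRUE)$maximum * 1000
  expect_lt(abs((dp - 1) / fs * 1000 - true_max), 10)
})

test_that("without a diastolic wave the notch is absent (class 4) and there
           is no diastolic peak", {
  fs <- 1000
  proc <- analytic_proc(fs, 1, centers = 0.3, amps = 1, sigmas = 0.1)
  pulse <- list(on = 1L, sp = which.max(proc$ppg), off = 1000L)
  pts <- detect_derivative_points(proc, pulse)
  dn <- detect_dicrotic_notch(proc, pulse, pts)
  expect_equal(dn$dn_class, 4L)
  expect_true(is.na(detect_diastolic_peak(proc, pulse, c(pts, dn))))
})

test_that("a merged shallow diastolic wave gives a class-3 notch at the
           second-derivative zero-crossing", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 12, fs = 1000,
                                           sys_sigma = 0.12, ref_amp = 0.5,
                                           ref_mu = 0.45, ref_sigma = 0.08,
                                           dia_amp = 0.3, dia_mu = 0.62,
                                           dia_sigma = 0.05))
  res <- ppg_pipeline(g$signal)
  gt <- g$ground_truth
  expect_true(all(res$fiducials$dn_class == 3))
  det_dn <- (res$fiducials$dn - 1) / res$fs * 1000
  det_sp <- (res$fiducials$sp - 1) / res$fs * 1000
  m <- vapply(det_sp, function(s) which.min(abs(gt$sp - s)), integer(1))
  expect_lt(max(abs(det_dn - gt$dn[m])), 10)
})

test_that("detections match a brute-force scan of the definitions within one
           sample on clean high-rate pulses", {
  pts <- c("on", "sp", "dn", "dp", "off", "u", "v", "w",
           "a", "b", "c", "d", "e", "f", "p1", "p2")
  shapes <- list(
    synth_config(hr = 60, duration = 10, fs = 1000),
    synth_config(hr = 60, duration = 10, fs = 1000, dia_amp = 0,
                 sys_sigma = 0.08),
    synth_config(hr = 60, duration = 10, fs = 1000, sys_sigma = 0.12,
                 ref_amp = 0.5, ref_mu = 0.45, ref_sigma = 0.08,
                 dia_amp = 0.5, dia_mu = 0.62, dia_sigma = 0.05))
  for (cfg in shapes) {
    g <- generate_synthetic_ppg(cfg)
    proc <- preprocess_signal(g$signal)
    pulses <- detect_onsets_offsets(proc, detect_beats(proc))
    fid <- detect_fiducials(proc, pulses, correction = FALSE)
    for (i in seq_len(nrow(fid))) {
      bf <- bf_fiducials(proc, fid$on[i], fid$sp[i], fid$off[i])
      for (p in pts) {
        det <- fid[[p]][i]; ref <- bf[[p]]
        expect_true(is.na(det) == is.na(ref),
                    info = sprintf("presence of %s, pulse %d", p, i))
        if (!is.na(det) && !is.na(ref))
          expect_lte(abs(det - ref), 1,
                     label = sprintf("point %s pulse %d: |%d - %d|",
                                     p, i, det, ref))
      }
    }
  }
})

test_that("correction enforces ordering, is idempotent, and passes through
           when disabled", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 20, fs = 256,
                                           noise_snr_db = 25, seed = 3))
  proc <- preprocess_signal(g$signal)
  pulses <- detect_onsets_offsets(proc, detect_beats(proc))
  raw <- detect_fiducials(proc, pulses, correction = FALSE)
  corr <- correct_fiducials(raw, proc = proc, enabled = TRUE)
  # passthrough and idempotence
  expect_identical(correct_fiducials(raw, proc = proc, enabled = FALSE), raw)
  expect_identical(correct_fiducials(corr, proc = proc, enabled = TRUE), corr)
  # ordering invariants hold for every corrected pulse
  ok <- function(x) all(x, na.rm = TRUE)
  expect_true(ok(corr$on <= corr$u & corr$u <= corr$sp))
  expect_true(ok(corr$sp <= corr$dn & corr$dn <= corr$off))
  expect_true(ok(corr$dn <= corr$dp))
  expect_true(ok(corr$a < corr$b & corr$b <= corr$e & corr$e < corr$f))

  # an inconsistent diastolic peak (before the notch) is recomputed/discarded
  fake <- raw[1, ]
  fake$dp <- fake$sp + 1L
  fake$dn <- fake$sp + 10L
  fixed <- correct_fiducials(fake, proc = NULL, enabled = TRUE)
  expect_true(is.na(fixed$dp) || fixed$dp > fixed$dn)
})

test_that("each fiducial appears at most once per pulse", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 15, fs = 256))
  proc <- preprocess_signal(g$signal)
  fid <- detect_fiducials(proc, detect_onsets_offsets(proc, detect_beats(proc)))
  expect_equal(anyDuplicated(fid$pulse), 0)
  expect_true(all(vapply(seq_len(nrow(fid)), function(i)
    length(fid$sp[i]) == 1, logical(1))))
})
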