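test_that("the biomarker set has exactly 74 members in four groups", {
  nms <- biomarker_names()
  expect_length(nms, 74)
  expect_equal(anyDuplicated(nms), 0)
})

test_that("pulse widths follow linear geometry on a triangle", {
  fs <- 1000
  # symmetric triangle: onset at 0, peak 1.0 at 100 ms, offset at 200 ms
  ppg <- c(seq(0, 1, length.out = 101), seq(1, 0, length.out = 101)[-1])
  w <- pulse_width_at_x(ppg, on = 1L, sp = 101L, off = 201L, fs = fs, x = 50)
  expect_equal(w$Tswx, 50)
  expect_equal(w$Tdwx, 50)
  expect_equal(w$Tpwx, 100)
  w100 <- pulse_width_at_x(ppg, 1L, 101L, 201L, fs, x = 100)
  expect_equal(w100$Tpwx, 0)

  # the same triangle sampled at 50 Hz: interpolated crossings stay within 1 ms
  fs2 <- 50
  t2 <- seq(0, 0.2, by = 1 / fs2)
  ppg2 <- ifelse(t2 <= 0.1, t2 / 0.1, (0.2 - t2) / 0.1)
  w2 <- pulse_width_at_x(ppg2, 1L, which.max(ppg2), length(ppg2), fs2, x = 50)
  expect_equal(w2$Tswx, 50, tolerance = 1)
  expect_equal(w2$Tdwx, 50, tolerance = 1)
})

test_that("ratio formulas reproduce hand-computed values", {
  # fabricated pulse with known fiducials and derivative amplitudes
  fs <- 1000
  n <- 1100
  proc <- structure(list(ppg = numeric(n), d1 = numeric(n), d2 = numeric(n),
                         d3 = numeric(n), fs = fs, warmup_s = 0),
                    class = "processed_ppg")
  fid <- list(on = 1L, sp = 301L, dn = 501L, dp = 601L, off = 1001L,
              u = 200L, v = 400L, w = 550L, a = 250L, b = 320L, c = 380L,
              d = 450L, e = 480L, f = 560L, p1 = 340L, p2 = 430L)
  proc$ppg[1:1001] <- sin(pi * (0:1000) / 1000)  # smooth arch, zero at ends
  proc$d2[c(250, 320, 380, 450, 480)] <- c(1.0, -0.8, -0.2, -0.3, 0.4)
  bm <- compute_beat_biomarkers(proc, fid, next_sp = NA_integer_)

  expect_equal(unname(bm["Tpi"]), 1000)
  expect_equal(unname(bm["IPR"]), 60)            # 60 / (1 s pulse interval)
  expect_equal(unname(bm["AGI"]), -0.7)          # (Ab - Ac - Ad - Ae) / Aa
  expect_equal(unname(bm["AGImod"]), -0.3)
  expect_equal(unname(bm["AGIinf"]), -1.2)
  expect_equal(unname(bm["(Ac-Ab)/Aa"]), 0.6)
  expect_equal(unname(bm["(Ad-Ab)/Aa"]), 0.5)
  # IPA and IPAD identities
  expect_equal(unname(bm["IPA"]), unname(bm["AUCdia"] / bm["AUCsys"]))
  expect_equal(unname(bm["IPAD"]), unname(bm["IPA"] + bm["Ad/Aa"]))
  # area additivity under the trapezoidal rule
  expect_equal(unname(bm["AUCpi"]), unname(bm["AUCsys"] + bm["AUCdia"]))
  # width sum identity
  expect_equal(unname(bm["Tpw50"]), unname(bm["Tsw50"] + bm["Tdw50"]))
})

test_that("a complete fiducial set yields all 74 biomarkers; absent fiducials
           propagate to absent biomarkers, not zeros", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 15, fs = 500,
                                           sys_sigma = 0.12, ref_amp = 0.5,
                                           ref_mu = 0.45, ref_sigma = 0.08,
                                           dia_amp = 0.5, dia_mu = 0.62,
                                           dia_sigma = 0.05))
  proc <- preprocess_signal(g$signal)
  fid <- detect_fiducials(proc, detect_onsets_offsets(proc, detect_beats(proc)))
  bm <- compute_biomarkers(proc, fid)
  expect_equal(ncol(bm) - 1L, 74)
  mid <- which(rowSums(is.na(bm)) == 0)
  expect_gt(length(mid), 0)        # interior beats have every biomarker

  # dropping the notch removes every notch-dependent biomarker
  fid2 <- fid
  fid2$dn <- NA_integer_
  bm2 <- compute_beat_biomarkers(proc, fid2[2, ], next_sp = fid2$sp[3])
  expect_true(all(is.na(bm2[c("Tsys", "Tdia", "Adn", "AUCsys", "AUCdia",
                              "IPA", "Tsys/Tdia", "IPAD")])))
  expect_false(anyNA(bm2[c("Tpi", "Tsp", "Asp")]))
})

test_that("pure-time biomarkers and amplitude ratios are scale invariant", {
  g <- generate_synthetic_ppg(synth_config(hr = 60, duration = 15, fs = 256))
  proc <- preprocess_signal(g$signal)
  fid <- detect_fiducials(proc, detect_onsets_offsets(proc, detect_beats(proc)))
  bm1 <- compute_beat_biomarkers(proc, fid[2, ], next_sp = fid$sp[3])
  proc2 <- proc
  for (ch in c("ppg", "d1", "d2", "d3")) proc2[[ch]] <- 3 * proc2[[ch]]
  bm2 <- compute_beat_biomarkers(proc2, fid[2, ], next_sp = fid$sp[3])
  time_like <- c("Tpi", "Tpp", "Tsys", "Tdia", "Tsp", "Tdp", "dT", "Tsw50",
                 "Tdw50", "Tpw50", "IPR", "Tu", "Tv", "Ta", "Tb", "Te", "Tp1")
  ratios <- c("RI", "IPA", "Asp/Aoff", "Ab/Aa", "Ae/Aa", "AGI", "AGIinf",
              "AI", "Ap2/Ap1", "Au/Asp")
  for (nm in c(time_like, ratios))
    expect_equal(unname(bm1[nm]), unname(bm2[nm]), tolerance = 1e-9,
                 label = nm)
})

test_that("the nine summary statistics follow their stated conventions", {
  df <- data.frame(x = c(1, 2, 3, 4, 5))
  s <- summarize_biomarkers(df)
  expect_equal(names(s), c("biomarker", "AVG", "MED", "SD", "Q1", "Q3",
                           "IQR", "SKW", "KUR", "MAD"))
  expect_equal(s$AVG, 3); expect_equal(s$MED, 3)
  expect_equal(s$Q1, 2); expect_equal(s$Q3, 4); expect_equal(s$IQR, 2)
  expect_equal(s$MAD, 1.2)
  expect_equal(s$SD, sd(1:5))

  cns <- summarize_biomarkers(data.frame(k = rep(7, 10)))
  expect_equal(cns$SD, 0); expect_equal(cns$IQR, 0)
  expect_equal(cns$SKW, 0); expect_equal(cns$KUR, 0)

  # moment-formula oracle for skewness/kurtosis on a log-normal sample
  set.seed(19)
  v <- rlnorm(1000, 0, 0.5)
  s2 <- summarize_biomarkers(data.frame(v = v))
  n <- length(v); m <- mean(v)
  m2 <- mean((v - m)^2); m3 <- mean((v - m)^3); m4 <- mean((v - m)^4)
  g1 <- m3 / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  G2 <- ((n + 1) * (m4 / m2^2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(s2$SKW, G1, tolerance = 0.05)
  expect_equal(s2$KUR, G2, tolerance = 0.05)

  # an all-absent biomarker produces no summary row
  s3 <- summarize_biomarkers(data.frame(a = c(1, 2, 3), b = c(NA, NA, NA)))
  expect_equal(s3$biomarker, "a")
  # quartile ordering invariant
  expect_true(all(s3$Q1 <= s3$MED & s3$MED <= s3$Q3))
})
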