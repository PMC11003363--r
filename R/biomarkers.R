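#' Names of the 74 pulse-wave biomarkers
#'
#' The biomarkers fall into four groups: PPG Signal (17: intervals,
#' amplitudes, areas), Signal Ratios (12), PPG Derivatives (15: timing of the
#' derivative fiducials) and Derivatives Ratios (30: interval ratios,
#' amplitude ratios including the aging and augmentation indices, and combined
#' quantities).
#'
#' @param x Width percentage used for the systolic/diastolic/pulse width
#'   triple (appears in the corresponding names).
#' @return Character vector of length 74.
#' @export
biomarker_names <- function(x = 50) {
  sw <- paste0("Tsw", x); dw <- paste0("Tdw", x); pw <- paste0("Tpw", x)
  c(
    # PPG Signal (17)
    "Tpi", "Tpp", "Tsys", "Tdia", "Tsp", "Tdp", "dT", sw, dw, pw,
    "Asp", "Adn", "Adp", "Aoff", "AUCpi", "AUCsys", "AUCdia",
    # Signal Ratios (12)
    "IPR", "Tsys/Tdia", paste0(pw, "/Tpi"), paste0(pw, "/Tsp"),
    paste0(dw, "/", sw), "Tsp/Tpi", "Asp/Aoff", "RI", "IPA", "Tsp/Asp",
    "SI", "Asp/(Tpi-Tsp)",
    # PPG Derivatives (15)
    "Tu", "Tv", "Tw", "Ta", "Tb", "Tc", "Td", "Te", "Tf", "Tb-c", "Tb-d",
    "Tp1", "Tp2", "Tp1-dp", "Tp2-dp",
    # Derivatives Ratios (30)
    "Tu/Tpi", "Tv/Tpi", "Tw/Tpi", "Ta/Tpi", "Tb/Tpi", "Tc/Tpi", "Td/Tpi",
    "Te/Tpi", "Tf/Tpi", "(Tu-Ta)/Tpi", "(Tv-Tb)/Tpi",
    "Au/Asp", "Av/Au", "Aw/Au", "Ab/Aa", "Ac/Aa", "Ad/Aa", "Ae/Aa", "Af/Aa",
    "Ap2/Ap1", "(Ac-Ab)/Aa", "(Ad-Ab)/Aa", "AGI", "AGImod", "AGIinf", "AI",
    "RIp1", "RIp2", "SC", "IPAD"
  )
}

# NA-safe division: absent operand or zero denominator yields NA
sdiv <- function(a, b) {
  out <- rep(NA_real_, max(length(a), length(b)))
  ok <- !is.na(a) & !is.na(b) & b != 0
  out[ok] <- a[ok] / b[ok]
  out
}

#' Pulse widths at x% of the systolic amplitude
#'
#' The threshold level is the onset amplitude plus x% of the systolic peak
#' amplitude. The systolic width is the time from the ascending crossing
#' (linearly interpolated between bracketing samples) to the peak; the
#' diastolic width from the peak to the descending crossing; the pulse width
#' is their sum. A side whose level is never crossed yields `NA`.
#'
#' @param ppg Filtered PPG vector (full record).
#' @param on,sp,off Sample indices of the pulse.
#' @param fs Sampling rate in Hz.
#' @param x Width percentage (0 < x <= 100).
#' @return List with `Tswx`, `Tdwx`, `Tpwx` in ms.
#' @export
pulse_width_at_x <- function(ppg, on, sp, off, fs, x = 50) {
  stopifnot(x > 0, x <= 100)
  base <- ppg[on]
  level <- base + x / 100 * (ppg[sp] - base)
  cross_up <- function(lo, hi) {  # last upward crossing before hi
    i <- lo:(hi - 1L)
    hit <- which(ppg[i] <= level & ppg[i + 1L] > level)
    if (!length(hit)) return(NA_real_)
    j <- i[hit[length(hit)]]
    j + (level - ppg[j]) / (ppg[j + 1L] - ppg[j])
  }
  cross_down <- function(lo, hi) {  # first downward crossing after lo
    i <- lo:(hi - 1L)
    hit <- which(ppg[i] >= level & ppg[i + 1L] < level)
    if (!length(hit)) return(NA_real_)
    j <- i[hit[1L]]
    j + (ppg[j] - level) / (ppg[j] - ppg[j + 1L])
  }
  tsw <- tdw <- NA_real_
  if (x == 100) { tsw <- 0; tdw <- 0 }
  else {
    cu <- if (sp > on) cross_up(on, sp) else NA_real_
    if (!is.na(cu)) tsw <- (sp - cu) / fs * 1000
    cd <- if (off > sp) cross_down(sp, off) else NA_real_
    if (!is.na(cd)) tdw <- (cd - sp) / fs * 1000
  }
  list(Tswx = tsw, Tdwx = tdw,
       Tpwx = if (is.na(tsw) || is.na(tdw)) NA_real_ else tsw + tdw)
}

#' Compute the 74 biomarkers for one pulse
#'
#' Timings are ms from the pulse onset; amplitudes of PPG fiducials are
#' measured relative to the onset amplitude; derivative amplitudes (`Au`,
#' `Av`, ..., `Ap1`, `Ap2`) are read off the respective derivative series at
#' the point's sample, in derivative units. Areas are trapezoidal integrals of
#' the onset-referenced pulse in amplitude x ms. A biomarker whose required
#' fiducials are absent, or whose denominator is zero, is `NA`.
#'
#' @param proc A `"processed_ppg"`.
#' @param fid One-row data frame (or list) of fiducial sample indices.
#' @param next_sp Systolic-peak index of the following pulse (for the
#'   peak-to-peak interval), or `NA`.
#' @param x Width percentage.
#' @return Named numeric vector of length 74.
#' @export
compute_beat_biomarkers <- function(proc, fid, next_sp = NA_integer_, x = 50) {
  fs <- proc$fs
  P <- proc$ppg
  g <- function(nm) {
    v <- fid[[nm]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_integer_ else as.integer(v)
  }
  on <- g("on"); sp <- g("sp"); dn <- g("dn"); dp <- g("dp"); off <- g("off")
  tms <- function(i) if (is.na(i)) NA_real_ else (i - on) / fs * 1000
  A <- function(i) if (is.na(i)) NA_real_ else P[i] - P[on]

  Tpi <- tms(off)
  Tpp <- if (is.na(next_sp)) NA_real_ else (next_sp - sp) / fs * 1000
  Tsys <- tms(dn)
  Tdia <- if (is.na(dn)) NA_real_ else Tpi - Tsys
  Tsp <- tms(sp); Tdp <- tms(dp)
  dT <- if (is.na(dp)) NA_real_ else Tdp - Tsp
  wd <- pulse_width_at_x(P, on, sp, off, fs, x)

  Asp <- A(sp); Adn <- A(dn); Adp <- A(dp); Aoff <- A(off)

  auc <- function(i, j) {
    if (is.na(i) || is.na(j) || j <= i) return(NA_real_)
    seg <- i:j
    trapz_int((seg - on) / fs * 1000, P[seg] - P[on])
  }
  AUCpi <- auc(on, off); AUCsys <- auc(on, dn); AUCdia <- auc(dn, off)

  dv <- function(series, nm) { i <- g(nm); if (is.na(i)) NA_real_ else series[i] }
  Au <- dv(proc$d1, "u"); Av <- dv(proc$d1, "v"); Aw <- dv(proc$d1, "w")
  Aa <- dv(proc$d2, "a"); Ab <- dv(proc$d2, "b"); Ac <- dv(proc$d2, "c")
  Ad <- dv(proc$d2, "d"); Ae <- dv(proc$d2, "e"); Af <- dv(proc$d2, "f")
  Ap1 <- dv(proc$d3, "p1"); Ap2 <- dv(proc$d3, "p2")

  Tu <- tms(g("u")); Tv <- tms(g("v")); Tw <- tms(g("w"))
  Ta <- tms(g("a")); Tb <- tms(g("b")); Tc <- tms(g("c")); Td <- tms(g("d"))
  Te <- tms(g("e")); Tf <- tms(g("f")); Tp1 <- tms(g("p1")); Tp2 <- tms(g("p2"))

  vals <- c(
    Tpi, Tpp, Tsys, Tdia, Tsp, Tdp, dT, wd$Tswx, wd$Tdwx, wd$Tpwx,
    Asp, Adn, Adp, Aoff, AUCpi, AUCsys, AUCdia,
    sdiv(60000, Tpi), sdiv(Tsys, Tdia), sdiv(wd$Tpwx, Tpi),
    sdiv(wd$Tpwx, Tsp), sdiv(wd$Tdwx, wd$Tswx), sdiv(Tsp, Tpi),
    sdiv(Asp, Aoff), sdiv(Adp, Asp), sdiv(AUCdia, AUCsys), sdiv(Tsp, Asp),
    sdiv(Asp, dT), sdiv(Asp, Tpi - Tsp),
    Tu, Tv, Tw, Ta, Tb, Tc, Td, Te, Tf, Tb - Tc, Tb - Td, Tp1, Tp2,
    Tp1 - Tdp, Tp2 - Tdp,
    sdiv(Tu, Tpi), sdiv(Tv, Tpi), sdiv(Tw, Tpi), sdiv(Ta, Tpi),
    sdiv(Tb, Tpi), sdiv(Tc, Tpi), sdiv(Td, Tpi), sdiv(Te, Tpi),
    sdiv(Tf, Tpi), sdiv(Tu - Ta, Tpi), sdiv(Tv - Tb, Tpi),
    sdiv(Au, Asp), sdiv(Av, Au), sdiv(Aw, Au), sdiv(Ab, Aa), sdiv(Ac, Aa),
    sdiv(Ad, Aa), sdiv(Ae, Aa), sdiv(Af, Aa), sdiv(Ap2, Ap1),
    sdiv(Ac - Ab, Aa), sdiv(Ad - Ab, Aa),
    sdiv(Ab - Ac - Ad - Ae, Aa), sdiv(Ab - Ac - Ad, Aa), sdiv(Ab - Ae, Aa),
    {
      p1i <- g("p1"); p2i <- g("p2")
      if (is.na(p1i) || is.na(p2i) || is.na(Asp) || Asp == 0) NA_real_
      else (P[p2i] - P[p1i]) / Asp
    },
    sdiv(Adp, A(g("p1"))), sdiv(Adp, A(g("p2"))),
    {
      sc_den <- sdiv(Asp - Au, Asp)
      d2sp <- if (is.na(sp)) NA_real_ else proc$d2[sp]
      sdiv(d2sp, sc_den)
    },
    {
      ipa <- sdiv(AUCdia, AUCsys); nd <- sdiv(Ad, Aa)
      if (is.na(ipa) || is.na(nd)) NA_real_ else ipa + nd
    }
  )
  stats::setNames(vals, biomarker_names(x))
}

#' Per-beat biomarker matrix for a record
#'
#' Applies [compute_beat_biomarkers()] to every (by default, every valid)
#' pulse.
#'
#' @param proc A `"processed_ppg"`.
#' @param fiducials Data frame from [detect_fiducials()].
#' @param x Width percentage.
#' @param valid_only Drop pulses flagged invalid by the duration constraints.
#' @return Data frame: `pulse` column plus 74 biomarker columns, one row per
#'   beat.
#' @export
compute_biomarkers <- function(proc, fiducials, x = 50, valid_only = TRUE) {
  fid <- fiducials
  if (valid_only && "valid" %in% names(fid)) fid <- fid[fid$valid, , drop = FALSE]
  n <- nrow(fid)
  nxt <- c(fid$sp[-1L], NA_integer_)
  # peak-to-peak only meaningful across adjacent retained pulses
  if (n > 1L) nxt[which(diff(fid$pulse) != 1L)] <- NA_integer_
  m <- t(vapply(seq_len(n), function(i)
    compute_beat_biomarkers(proc, fid[i, ], next_sp = nxt[i], x = x),
    numeric(74)))
  out <- as.data.frame(m, check.names = FALSE)
  cbind(pulse = fid$pulse, out)
}

#' Nine summary statistics per biomarker
#'
#' For each biomarker, over the non-absent per-beat values: mean (AVG), median
#' (MED), standard deviation (SD, n-1 denominator), lower/upper quartiles
#' (Q1, Q3, linear interpolation of the empirical CDF), inter-quartile range
#' (IQR), adjusted Fisher-Pearson skewness (SKW), excess kurtosis (KUR), and
#' the mean absolute deviation from the mean (MAD). Degenerate columns
#' (zero variance) report SKW = KUR = 0; biomarkers with no observed values
#' are omitted.
#'
#' @param biomarkers Per-beat biomarker data frame from [compute_biomarkers()]
#'   (a `pulse` column, if present, is ignored).
#' @return Data frame with one row per biomarker and columns `biomarker`,
#'   `AVG`, `MED`, `SD`, `Q1`, `Q3`, `IQR`, `SKW`, `KUR`, `MAD`.
#' @export
summarize_biomarkers <- function(biomarkers) {
  cols <- setdiff(names(biomarkers), "pulse")
  rows <- lapply(cols, function(nm) {
    v <- biomarkers[[nm]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NULL)
    s <- stats::sd(v)
    if (is.na(s)) s <- 0
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    skw <- if (s == 0 || length(v) < 3) 0 else e1071::skewness(v, type = 2)
    kur <- if (s == 0 || length(v) < 4) 0 else e1071::kurtosis(v, type = 2)
    data.frame(biomarker = nm, AVG = mean(v), MED = stats::median(v), SD = s,
               Q1 = q[1L], Q3 = q[2L], IQR = q[2L] - q[1L],
               SKW = skw, KUR = kur, MAD = mean(abs(v - mean(v))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
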