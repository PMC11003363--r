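#' Run the full pulse-wave analysis pipeline
#'
#' Preprocessing, systolic-peak detection, pulse segmentation, fiducial-point
#' detection (with optional correction), biomarker engineering and summary
#' statistics, and the optional per-pulse quality index.
#'
#' @param raw Raw signal (list with `samples`, `fs`), e.g. from
#'   [load_signal()] or [generate_synthetic_ppg()].
#' @param filter_cfg A [filter_config()].
#' @param detector_cfg A [detector_config()].
#' @param correction Apply the fiducial correction pass.
#' @param sqi Also compute the signal-quality index.
#' @param width_x Width percentage for the pulse-width biomarkers.
#' @return An object of class `"ppg_analysis"`: `proc`, `beats`, `pulses`,
#'   `fiducials`, `biomarkers`, `summary`, `sqi` (or `NULL`), `fs`.
#' @export
ppg_pipeline <- function(raw, filter_cfg = filter_config(),
                         detector_cfg = detector_config(),
                         correction = TRUE, sqi = FALSE, width_x = 50) {
  proc <- preprocess_signal(raw, filter_cfg)
  beats <- detect_beats(proc, detector_cfg)
  pulses <- detect_onsets_offsets(proc, beats)
  if (nrow(pulses) == 0) {
    return(structure(list(proc = proc, beats = beats, pulses = pulses,
                          fiducials = NULL, biomarkers = NULL, summary = NULL,
                          sqi = NULL, fs = proc$fs),
                     class = "ppg_analysis"))
  }
  fid <- detect_fiducials(proc, pulses, correction = correction)
  bm <- compute_biomarkers(proc, fid, x = width_x)
  sm <- summarize_biomarkers(bm)
  q <- if (sqi) compute_sqi(proc, pulses)$sqi else NULL
  structure(list(proc = proc, beats = beats, pulses = pulses, fiducials = fid,
                 biomarkers = bm, summary = sm, sqi = q, fs = proc$fs),
            class = "ppg_analysis")
}

#' @export
print.ppg_analysis <- function(x, ...) {
  cat("PPG analysis (", length(x$proc$ppg), " samples @ ", x$fs, " Hz)\n",
      sep = "")
  cat("  beats detected:  ", length(x$beats$sp_idx), "\n", sep = "")
  cat("  pulses retained: ",
      if (is.null(x$fiducials)) 0 else sum(x$fiducials$valid), " valid / ",
      nrow(x$pulses), "\n", sep = "")
  if (!is.null(x$biomarkers))
    cat("  biomarkers:      ", ncol(x$biomarkers) - 1L, " per beat, ",
        nrow(x$summary), " summarized\n", sep = "")
  invisible(x)
}
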