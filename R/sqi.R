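#' Template-matching signal-quality index
#'
#' Each pulse is resampled to a fixed length, the template is the pointwise
#' mean beat shape, and a pulse's quality is its Pearson correlation with the
#' template, clipped below at zero -- a unitless index in \[0, 1\]. Because
#' correlation is invariant to amplitude scaling and baseline offset, so is
#' the index. It is informational only and gates no other stage.
#'
#' @param proc A `"processed_ppg"`.
#' @param pulses Data frame from [detect_onsets_offsets()] (columns `on`,
#'   `off`).
#' @param L Template length in samples.
#' @return List with `sqi` (numeric per pulse; all `NA` when fewer than two
#'   pulses are available) and `template`.
#' @export
compute_sqi <- function(proc, pulses, L = 100L) {
  n <- nrow(pulses)
  if (n < 2L)
    return(list(sqi = rep(NA_real_, n), template = NULL))
  beats <- t(vapply(seq_len(n), function(i) {
    seg <- proc$ppg[pulses$on[i]:pulses$off[i]]
    stats::approx(seq_along(seg), seg, n = L)$y
  }, numeric(L)))
  template <- colMeans(beats)
  sqi <- vapply(seq_len(n), function(i) {
    b <- beats[i, ]
    if (stats::sd(b) == 0 || stats::sd(template) == 0) return(0)
    max(0, stats::cor(b, template))
  }, numeric(1))
  list(sqi = sqi, template = template)
}
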