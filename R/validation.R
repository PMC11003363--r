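#' Align two event trains and score the match
#'
#' Finds the constant lag (within `max_lag_ms`, via cross-correlation of the
#' event trains binarized at 10 ms) that maximizes the number of one-to-one
#' matches, then matches detected to reference events greedily by nearest
#' absolute difference (ties resolved toward the earlier reference event)
#' within `tolerance_ms`. Sensitivity, positive predictive value and their
#' harmonic mean (F1) are reported in percent.
#'
#' @param detected,reference Event times in ms (sorted).
#' @param tolerance_ms Match tolerance in ms.
#' @param max_lag_ms Maximum alignment lag searched in ms (0 disables
#'   alignment).
#' @return List: `TP`, `FP`, `FN`, `Se`, `PPV`, `F1` (percent), `lag_ms`.
#' @export
align_and_match <- function(detected, reference, tolerance_ms = 150,
                            max_lag_ms = 0) {
  detected <- sort(detected); reference <- sort(reference)
  if (!length(reference)) {
    warning("empty reference train: sensitivity undefined, F1 = 0")
    return(list(TP = 0L, FP = length(detected), FN = 0L,
                Se = NA_real_, PPV = if (length(detected)) 0 else NA_real_,
                F1 = 0, lag_ms = 0))
  }
  lag <- 0
  if (max_lag_ms > 0 && length(detected)) {
    bin <- 10
    lo <- min(detected, reference); hi <- max(detected, reference)
    nb <- as.integer(ceiling((hi - lo) / bin)) + 1L
    bd <- tabulate(pmin(nb, floor((detected - lo) / bin) + 1L), nb)
    br <- tabulate(pmin(nb, floor((reference - lo) / bin) + 1L), nb)
    lags <- seq(-round(max_lag_ms / bin), round(max_lag_ms / bin))
    score <- vapply(lags, function(k) {
      if (k >= 0) sum(bd[seq_len(nb - k)] * br[seq_len(nb - k) + k])
      else sum(bd[seq_len(nb + k) - k] * br[seq_len(nb + k)])
    }, numeric(1))
    best <- lags[score == max(score)]
    lag <- -best[which.min(abs(best))] * bin
  }
  da <- detected - lag
  # greedy one-to-one nearest matching
  pairs <- NULL
  if (length(da)) {
    cand <- do.call(rbind, lapply(seq_along(da), function(i) {
      d <- abs(da[i] - reference)
      j <- which(d <= tolerance_ms)
      if (length(j)) cbind(i = i, j = j, d = d[j]) else NULL
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand[, "d"], reference[cand[, "j"]]), , drop = FALSE]
      used_i <- logical(length(da)); used_j <- logical(length(reference))
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, "i"]; j <- cand[r, "j"]
        if (!used_i[i] && !used_j[j]) { used_i[i] <- used_j[j] <- TRUE; keep[r] <- TRUE }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  TP <- if (is.null(pairs)) 0L else nrow(pairs)
  FP <- length(detected) - TP
  FN <- length(reference) - TP
  Se <- 100 * TP / (TP + FN)
  PPV <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  F1 <- if (!is.na(Se) && !is.na(PPV) && Se + PPV > 0)
    2 * Se * PPV / (Se + PPV) else 0
  list(TP = TP, FP = as.integer(FP), FN = as.integer(FN),
       Se = Se, PPV = PPV, F1 = F1, lag_ms = lag)
}

#' Fiducial-point error statistics against reference annotations
#'
#' For each fiducial point, over the pulses where both detection and
#' annotation are present: the mean absolute error, the standard deviation of
#' the absolute errors, the signed bias, and the Bland-Altman limits of
#' agreement (bias +/- 1.96 SD of the signed differences), all in ms.
#'
#' @param detected,annotated Data frames with one row per pulse and one column
#'   per fiducial point holding times in ms (rows are matched by position).
#' @param points Fiducial columns to evaluate (default: the columns the two
#'   frames share).
#' @return Data frame: `point`, `n`, `mae`, `sd_ae`, `bias`, `loa_low`,
#'   `loa_high`.
#' @export
fiducial_errors <- function(detected, annotated, points = NULL) {
  stopifnot(nrow(detected) == nrow(annotated))
  if (is.null(points))
    points <- intersect(intersect(names(detected), names(annotated)),
                        fiducial_point_names())
  rows <- lapply(points, function(p) {
    e <- detected[[p]] - annotated[[p]]
    e <- e[!is.na(e)]
    if (!length(e)) return(NULL)
    ba <- bland_altman_stats(e)
    data.frame(point = p, n = length(e), mae = mean(abs(e)),
               sd_ae = if (length(e) > 1) stats::sd(abs(e)) else 0,
               bias = mean(e),
               loa_low = ba$loa_low %||% NA_real_,
               loa_high = ba$loa_high %||% NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean of the signed differences) and limits of agreement at
#' bias +/- 1.96 SD, covering about 95% of the differences under normality.
#'
#' @param differences Signed paired differences (ms or any unit).
#' @return List `bias`, `sd`, `loa_low`, `loa_high`, `n`; the limits are
#'   `NULL` when fewer than two differences are supplied.
#' @export
bland_altman_stats <- function(differences) {
  d <- differences[!is.na(differences)]
  n <- length(d)
  if (n < 2L)
    return(list(bias = if (n) mean(d) else NA_real_, sd = NULL,
                loa_low = NULL, loa_high = NULL, n = n))
  b <- mean(d); s <- stats::sd(d)
  list(bias = b, sd = s, loa_low = b - 1.96 * s, loa_high = b + 1.96 * s, n = n)
}

#' Bland-Altman plot
#'
#' Scatter of pairwise means against differences with the bias and limits of
#' agreement drawn as horizontal lines.
#'
#' @param a,b Paired measurements.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [bland_altman_stats()] of `a - b`.
#' @export
plot_bland_altman <- function(a, b, ...) {
  d <- a - b
  st <- bland_altman_stats(d)
  graphics::plot((a + b) / 2, d, xlab = "Mean", ylab = "Difference", ...)
  graphics::abline(h = st$bias, lty = 1)
  if (!is.null(st$loa_low))
    graphics::abline(h = c(st$loa_low, st$loa_high), lty = 2)
  invisible(st)
}
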