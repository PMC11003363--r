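# Internal helpers shared across modules: extremum scans, zero-crossings,
# index/time conversion. Indices are 1-based inside the package; the I/O layer
# converts to the 0-based convention used in written tables.

# Indices of strict local maxima/minima. A plateau counts once, at its first
# sample (deterministic tie-break).
local_extrema <- function(x, type = c("max", "min")) {
  type <- match.arg(type)
  if (type == "min") x <- -x
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(as.numeric(x))
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  mid <- 2:(k - 1L)
  hit <- r$values[mid] > r$values[mid - 1L] & r$values[mid] > r$values[mid + 1L]
  starts[mid][hit]
}

# Sample index nearest to each sign change of x; linear interpolation between
# the bracketing samples decides which neighbour is closer. Exact zeros are
# reported at their own sample.
zero_crossing_idx <- function(x) {
  n <- length(x)
  if (n < 2L) return(integer(0))
  s <- sign(x)
  i <- which(s[-n] * s[-1L] < 0)
  out <- integer(0)
  if (length(i)) {
    frac <- x[i] / (x[i] - x[i + 1L])
    out <- as.integer(ifelse(frac < 0.5, i, i + 1L))
  }
  sort(unique(c(out, which(s == 0))))
}

idx_to_ms <- function(idx, fs) (idx - 1) / fs * 1000

ms_to_samples <- function(ms, fs) as.integer(round(ms * fs / 1000))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral of y over x (used for pulse areas)
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# first element of v strictly greater than a and (optionally) <= b
first_in <- function(v, a, b = Inf) {
  v <- v[v > a & v <= b]
  if (length(v)) v[1L] else NA_integer_
}

last_in <- function(v, a, b) {
  v <- v[v >= a & v < b]
  if (length(v)) v[length(v)] else NA_integer_
}
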