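#' Load a raw PPG signal
#'
#' Reads a single-channel PPG from CSV/TXT (one sample per line, optional
#' single header line), a Level-4 MAT file (one named numeric vector plus an
#' optional scalar `fs` variable), or an EDF file (channel selected by label).
#' The sampling rate is taken from file metadata when the format carries it
#' (EDF header, MAT `fs` variable) and must be supplied otherwise.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (from the file extension), `"csv"`, `"txt"`,
#'   `"mat"`, `"edf"`.
#' @param fs Sampling rate in Hz (required for csv/txt; overrides nothing when
#'   the file provides one).
#' @param channel EDF channel label, or MAT variable name.
#' @return A raw-signal list: `samples`, `fs`, `start_time`, `source`.
#' @export
load_signal <- function(path, format = c("auto", "csv", "txt", "mat", "edf"),
                        fs = NULL, channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", txt = "txt", mat = "mat", edf = "edf",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  out <- switch(format,
    csv = ,
    txt = {
      if (is.null(fs)) stop("fs must be supplied for ", format, " input")
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines)]
      vals <- suppressWarnings(as.numeric(lines))
      if (length(vals) > 1L && is.na(vals[1L]) && !anyNA(vals[-1L])) {
        vals <- vals[-1L]  # single header line
      }
      if (anyNA(vals)) stop("non-numeric content in ", path)
      list(samples = vals, fs = fs)
    },
    mat = {
      vars <- read_mat4(path)
      file_fs <- if ("fs" %in% names(vars)) as.numeric(vars$fs[1L]) else fs
      if (is.null(file_fs)) stop("fs must be supplied: no 'fs' variable in ", path)
      nm <- channel %||% setdiff(names(vars), "fs")[1L]
      if (is.na(nm) || !nm %in% names(vars))
        stop("variable '", channel, "' not found in ", path)
      list(samples = as.numeric(vars[[nm]]), fs = file_fs)
    },
    edf = {
      if (is.null(channel)) stop("channel must be supplied for EDF input")
      read_edf_channel(path, channel)
    })
  if (!length(out$samples)) stop("no samples read from ", path)
  if (!all(is.finite(out$samples))) stop("non-finite samples in ", path)
  if (is.null(out$fs) || out$fs <= 0) stop("invalid sampling rate")
  list(samples = out$samples, fs = out$fs, start_time = 0, source = path)
}

# Minimal Level-4 (Matlab v4) MAT reader: little-endian double matrices only.
read_mat4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
    if (length(hdr) < 5L) break
    type <- hdr[1L]
    if (type %% 10 != 0 || type >= 10000)
      stop("unsupported MAT format (only Level-4 double matrices are read)")
    mrows <- hdr[2L]; ncols <- hdr[3L]; imagf <- hdr[4L]; namlen <- hdr[5L]
    nm <- readBin(con, "character", 1L)
    pad <- namlen - nchar(nm, type = "bytes") - 1L
    if (pad > 0) readBin(con, "raw", pad)
    vals <- readBin(con, "double", mrows * ncols, size = 8L, endian = "little")
    if (imagf) readBin(con, "double", mrows * ncols, size = 8L, endian = "little")
    out[[nm]] <- vals
  }
  out
}

# Minimal EDF reader: parses the fixed-width ASCII header, reads the int16
# data records and rescales to physical units.
read_edf_channel <- function(path, channel) {
  con <- file(path, "rb")
  on.exit(close(con))
  txt <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  num <- function(nc) as.numeric(txt(nc))
  txt(8L)                      # version
  txt(80L); txt(80L)           # patient / recording id
  txt(8L); txt(8L)             # start date / time
  txt(8L)                      # header bytes
  txt(44L)                     # reserved
  ndr <- num(8L)
  dur <- num(8L)
  ns <- as.integer(num(4L))
  labels <- vapply(seq_len(ns), function(i) txt(16L), character(1))
  for (i in seq_len(ns)) txt(80L)                       # transducer
  for (i in seq_len(ns)) txt(8L)                        # dimension
  phys_min <- vapply(seq_len(ns), function(i) num(8L), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) num(8L), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) num(8L), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) num(8L), numeric(1))
  for (i in seq_len(ns)) txt(80L)                       # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(num(8L)), integer(1))
  for (i in seq_len(ns)) txt(32L)                       # reserved
  ch <- which(labels == channel)
  if (!length(ch)) ch <- grep(channel, labels, fixed = TRUE)
  if (!length(ch))
    stop("channel '", channel, "' not found; available: ",
         paste(labels, collapse = ", "))
  ch <- ch[1L]
  rec_len <- sum(spr)
  raw <- readBin(con, "integer", ndr * rec_len, size = 2L, signed = TRUE,
                 endian = "little")
  offset <- c(0L, cumsum(spr))[ch]
  idx <- as.vector(outer(seq_len(spr[ch]) + offset,
                         (seq_len(ndr) - 1L) * rec_len, `+`))
  d <- raw[idx]
  scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  list(samples = (d - dig_min[ch]) * scale + phys_min[ch],
       fs = spr[ch] / dur)
}

#' Write / read a fiducial table
#'
#' One row per pulse; for each fiducial point a 0-based sample-index column
#' and a millisecond-from-onset column (empty cells for absent points), plus
#' the notch class, validity flag and optional per-pulse quality index.
#' Comma-separated, `.` decimal, UTF-8, header row. `read_fiducials()` inverts
#' the convention back to the package's 1-based indices.
#'
#' @param fiducials Data frame from [detect_fiducials()].
#' @param path Output CSV path.
#' @param fs Sampling rate in Hz (for the millisecond columns).
#' @param sqi Optional per-pulse quality values.
#' @return `path`, invisibly.
#' @export
write_fiducials <- function(fiducials, path, fs, sqi = NULL) {
  pts <- fiducial_point_names()
  out <- data.frame(pulse = fiducials$pulse)
  for (p in pts) {
    idx <- fiducials[[p]]
    out[[p]] <- as.integer(idx) - 1L
    out[[paste0(p, "_ms")]] <- round((idx - fiducials$on) / fs * 1000, 3)
  }
  out$dn_class <- fiducials$dn_class
  if ("valid" %in% names(fiducials)) out$valid <- fiducials$valid
  if (!is.null(sqi)) out$sqi <- round(sqi, 4)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fiducials
#' @return `read_fiducials()`: data frame with 1-based index columns,
#'   `dn_class` and (when present) `valid`/`sqi`.
#' @export
read_fiducials <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  for (p in fiducial_point_names()) d[[p]] <- as.integer(d[[p]]) + 1L
  d
}

#' Write biomarker tables
#'
#' The per-beat table has one row per pulse and one column per biomarker; the
#' summary table has one row per biomarker and the nine statistic columns.
#' Absent values are written as empty cells. With no beats, header-only tables
#' are produced.
#'
#' @param per_beat Data frame from [compute_biomarkers()].
#' @param summary Data frame from [summarize_biomarkers()] (or `NULL` to
#'   recompute from `per_beat`).
#' @param path_beats,path_summary Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_biomarkers <- function(per_beat, summary = NULL, path_beats,
                             path_summary) {
  if (is.null(summary)) summary <- summarize_biomarkers(per_beat)
  utils::write.csv(per_beat, path_beats, row.names = FALSE, na = "")
  if (is.null(summary))
    summary <- data.frame(biomarker = character(0), AVG = numeric(0),
                          MED = numeric(0), SD = numeric(0), Q1 = numeric(0),
                          Q3 = numeric(0), IQR = numeric(0), SKW = numeric(0),
                          KUR = numeric(0), MAD = numeric(0))
  utils::write.csv(summary, path_summary, row.names = FALSE, na = "")
  invisible(c(path_beats, path_summary))
}
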