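#' EDF and native recording I/O
#'
#' Recordings are exchanged as 16-bit EDF (European Data Format) files, the
#' standard clinical EEG container, or as a lossless native `rds` dialect
#' used internally so tests need not depend on EDF's 16-bit quantization.
#' The EDF writer stores one signal per channel with a shared physical
#' range symmetric about zero, so the quantization step is
#' `2 * phys_max / 65535` microvolts.
#'
#' @name recording-io
NULL

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

.edf_num <- function(x, width) .edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

#' Write a recording to disk
#'
#' @param rec a [recording]
#' @param path output path
#' @param format `"edf"` for 16-bit EDF, `"rds"` for the lossless native dialect
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path, format = c("edf", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(unclass(rec), path)
    return(invisible(path))
  }
  nch <- nrow(rec$data)
  ns <- ncol(rec$data)
  sr <- rec$sampling_rate_hz
  # one-second records when the rate is integral and divides the length,
  # otherwise a single record holding the whole signal
  if (ns == 0L) {
    spr <- max(1L, round(sr)); nrec <- 0L; recdur <- spr / sr
  } else if (abs(sr - round(sr)) < 1e-9 && ns %% round(sr) == 0L) {
    spr <- as.integer(round(sr)); nrec <- ns %/% spr; recdur <- 1
  } else {
    spr <- ns; nrec <- 1L; recdur <- ns / sr
  }
  phys_max <- max(1, ceiling(max(abs(rec$data), 0)))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.edf_pad("0", 8L))
  wr(.edf_pad(rec$subject_id, 80L))
  wr(.edf_pad(rec$record_id, 80L))
  wr(.edf_pad("01.01.00", 8L))
  wr(.edf_pad("00.00.00", 8L))
  wr(.edf_num(256L + 256L * nch, 8L))
  wr(.edf_pad("", 44L))
  wr(.edf_num(nrec, 8L))
  wr(.edf_num(round(recdur, 6), 8L))
  wr(.edf_num(nch, 4L))
  for (lab in rec$channel_names) wr(.edf_pad(paste("EEG", lab), 16L))
  for (i in seq_len(nch)) wr(.edf_pad("", 80L))
  for (i in seq_len(nch)) wr(.edf_pad("uV", 8L))
  for (i in seq_len(nch)) wr(.edf_num(-phys_max, 8L))
  for (i in seq_len(nch)) wr(.edf_num(phys_max, 8L))
  for (i in seq_len(nch)) wr(.edf_num(-32768L, 8L))
  for (i in seq_len(nch)) wr(.edf_num(32767L, 8L))
  for (i in seq_len(nch)) wr(.edf_pad("", 80L))
  for (i in seq_len(nch)) wr(.edf_num(spr, 8L))
  for (i in seq_len(nch)) wr(.edf_pad("", 32L))
  if (nrec > 0L) {
    scale <- 65535 / (2 * phys_max)
    dig <- round((rec$data + phys_max) * scale) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    for (r in seq_len(nrec)) {
      cols <- ((r - 1L) * spr + 1L):(r * spr)
      writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.edf_read_field <- function(con, width, name, numeric = FALSE) {
  raw <- readChar(con, width, useBytes = TRUE)
  if (nchar(raw, type = "bytes") < width)
    stop("truncated EDF header while reading field '", name, "'")
  val <- trimws(raw)
  if (numeric) {
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num))
      stop("EDF header field '", name, "' is not numeric: '", val, "'")
    return(num)
  }
  val
}

#' Read a recording from disk
#'
#' @param path input path
#' @param format `"edf"` or `"rds"` (see [write_recording])
#' @param validate_labels if `TRUE`, error on channel labels outside the
#'   standard 21-electrode 10/20 vocabulary
#' @return a [recording] in microvolts
#' @export
read_recording <- function(path, format = c("edf", "rds"),
                           validate_labels = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "rds") {
    x <- readRDS(path)
    rec <- recording(x$data, x$channel_names, x$sampling_rate_hz,
                     x$subject_id, x$record_id)
  } else {
    rec <- .read_edf(path)
  }
  if (validate_labels) {
    bad <- setdiff(rec$channel_names, STANDARD_21)
    if (length(bad) > 0L)
      stop("unknown channel label(s): ", paste(bad, collapse = ", "))
  }
  rec
}

.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  .edf_read_field(con, 8L, "version")
  subject <- .edf_read_field(con, 80L, "patient id")
  recid <- .edf_read_field(con, 80L, "recording id")
  .edf_read_field(con, 8L, "start date")
  .edf_read_field(con, 8L, "start time")
  .edf_read_field(con, 8L, "header bytes", numeric = TRUE)
  .edf_read_field(con, 44L, "reserved")
  nrec <- .edf_read_field(con, 8L, "number of data records", numeric = TRUE)
  recdur <- .edf_read_field(con, 8L, "data record duration", numeric = TRUE)
  nch <- as.integer(.edf_read_field(con, 4L, "number of signals",
                                    numeric = TRUE))
  if (nch < 1L) stop("EDF header field 'number of signals' must be >= 1")
  gethdr <- function(width, name, numeric = FALSE)
    vapply(seq_len(nch),
           function(i) .edf_read_field(con, width, paste0(name, "[", i, "]"),
                                       numeric = numeric),
           if (numeric) numeric(1) else character(1))
  labels <- gethdr(16L, "label")
  gethdr(80L, "transducer")
  gethdr(8L, "physical dimension")
  pmin_ <- as.numeric(gethdr(8L, "physical minimum", numeric = TRUE))
  pmax_ <- as.numeric(gethdr(8L, "physical maximum", numeric = TRUE))
  dmin <- as.numeric(gethdr(8L, "digital minimum", numeric = TRUE))
  dmax <- as.numeric(gethdr(8L, "digital maximum", numeric = TRUE))
  gethdr(80L, "prefiltering")
  spr <- as.integer(gethdr(8L, "samples per record", numeric = TRUE))
  gethdr(32L, "reserved per signal")
  if (any(dmax <= dmin))
    stop("EDF header field 'digital maximum' must exceed 'digital minimum'")
  if (recdur <= 0) stop("EDF header field 'data record duration' must be positive")
  labels <- sub("^EEG ", "", labels)
  nrec <- as.integer(nrec)
  out <- matrix(0, nrow = nch, ncol = max(0L, nrec) * spr[1L])
  if (nrec > 0L) {
    if (length(unique(spr)) != 1L)
      stop("EDF header field 'samples per record' differs across signals; unsupported")
    total <- nrec * nch * spr[1L]
    dig <- readBin(con, integer(), n = total, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(dig) < total)
      stop("truncated EDF data section (field 'number of data records' ",
           "promises more samples than the file holds)")
    dig <- array(dig, dim = c(spr[1L], nch, nrec))
    scale <- (pmax_ - pmin_) / (dmax - dmin)
    for (ch in seq_len(nch)) {
      out[ch, ] <- as.vector(dig[, ch, ]) * scale[ch] +
        pmin_[ch] - dmin[ch] * scale[ch]
    }
  }
  sr <- spr[1L] / recdur
  recording(out, labels, sr,
            subject_id = if (nzchar(subject)) subject else "unknown",
            record_id = if (nzchar(recid)) recid else "unknown")
}
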