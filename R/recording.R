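#' Construct a multichannel EEG recording
#'
#' A `recording` holds an ordered multichannel time series in microvolts
#' together with its sampling rate and subject/record identity. Data are
#' stored as a channels-by-samples matrix.
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolts)
#' @param channel_names character vector, one unique label per row of `data`
#' @param sampling_rate_hz positive sampling rate in Hz
#' @param subject_id,record_id identifiers carried through the pipeline
#' @return a `recording` object
#' @export
recording <- function(data, channel_names, sampling_rate_hz,
                      subject_id = "s000", record_id = "r000") {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_names))
    stop("data has ", nrow(data), " rows but ", length(channel_names),
         " channel names were given")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a single positive number")
  rownames(data) <- channel_names
  structure(list(subject_id = subject_id, record_id = record_id,
                 channel_names = channel_names,
                 sampling_rate_hz = sampling_rate_hz, data = data),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$record_id, nrow(x$data), ncol(x$data),
              x$sampling_rate_hz, ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording]
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sampling_rate_hz

#' Subset and reorder the channels of a recording to a montage
#'
#' Rows are subset and reordered to the montage's electrode order; the
#' sampling rate and identity are unchanged. All montage labels must be
#' present in the recording.
#'
#' @param rec a [recording]
#' @param montage a [montage] object or character vector of labels
#' @return a [recording] with `length(montage$names)` rows
#' @export
select_channels <- function(rec, montage) {
  labels <- if (inherits(montage, "montage")) montage$names else montage
  missing <- setdiff(labels, rec$channel_names)
  if (length(missing) > 0L)
    stop("channel(s) not present in recording: ",
         paste(missing, collapse = ", "))
  recording(rec$data[labels, , drop = FALSE], labels, rec$sampling_rate_hz,
            rec$subject_id, rec$record_id)
}

#' Crop a recording to a half-open time interval [t0, t1)
#'
#' @param rec a [recording]
#' @param t0,t1 interval bounds in seconds from record start
#' @export
crop_recording <- function(rec, t0, t1) {
  if (t0 < 0 || t1 > duration_s(rec) + 1e-9 || t0 >= t1)
    stop("invalid crop interval [", t0, ", ", t1, ")")
  i0 <- floor(t0 * rec$sampling_rate_hz) + 1L
  i1 <- floor(t1 * rec$sampling_rate_hz - 1e-9) + 1L
  recording(rec$data[, i0:i1, drop = FALSE], rec$channel_names,
            rec$sampling_rate_hz, rec$subject_id, rec$record_id)
}
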