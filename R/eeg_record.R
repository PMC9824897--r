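#' Multi-channel EEG record
#'
#' Container for a multi-channel EEG time series with its sampling rate and
#' seizure-interval annotations. Amplitudes are in microvolts; time
#' coordinates are seconds from record start, with intervals half-open
#' `[start, end)`.
#'
#' @param samples Numeric matrix, channels x time.
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param channel_names Character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param annotations Data frame with columns `onset_s` and `offset_s`
#'   (seconds from record start), one row per seizure. May have zero rows.
#'
#' @return An object of class `eeg_record` with fields `samples`,
#'   `sampling_rate_hz`, `channel_names`, `annotations`.
#' @export
eeg_record <- function(samples, sampling_rate_hz, channel_names = NULL,
                       annotations = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  storage.mode(samples) <- "double"
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (is.null(annotations)) {
    annotations <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  }
  rec <- structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         channel_names = as.character(channel_names),
         annotations = annotations[, c("onset_s", "offset_s"), drop = FALSE]),
    class = "eeg_record")
  validate_eeg_record(rec)
  rec
}

#' Validate an EEG record's invariants
#'
#' Checks that all channels have equal length, the sampling rate is positive,
#' and every annotation lies within `[0, duration]`.
#'
#' @param rec An `eeg_record`.
#' @return `rec`, invisibly; errors if an invariant is violated.
#' @export
validate_eeg_record <- function(rec) {
  if (!inherits(rec, "eeg_record")) stop("not an eeg_record")
  if (!is.matrix(rec$samples) || !is.numeric(rec$samples)) {
    stop("samples must be a numeric channels x time matrix")
  }
  if (anyNA(rec$samples)) stop("samples contain NA")
  if (length(rec$channel_names) != nrow(rec$samples)) {
    stop("channel_names length must equal the number of channels")
  }
  if (!is.finite(rec$sampling_rate_hz) || rec$sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive")
  }
  dur <- record_duration(rec)
  ann <- rec$annotations
  if (nrow(ann)) {
    ok <- ann$onset_s >= 0 & ann$onset_s < ann$offset_s & ann$offset_s <= dur + 1e-9
    if (!all(ok)) stop("annotations must satisfy 0 <= onset_s < offset_s <= duration")
  }
  invisible(rec)
}

#' Duration of a record in seconds
#' @param rec An `eeg_record`.
#' @return Duration in seconds.
#' @export
record_duration <- function(rec) ncol(rec$samples) / rec$sampling_rate_hz

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("eeg_record: %d channel(s), %.6g Hz, %.6g s, %d annotation(s)\n",
              nrow(x$samples), x$sampling_rate_hz, record_duration(x),
              nrow(x$annotations)))
  invisible(x)
}

#' Labelled analysis window cut from an EEG record
#'
#' @param samples Channels x window numeric matrix.
#' @param label `"preictal"` or `"interictal"`.
#' @param start_s Offset of the window in the source record, seconds.
#' @param source_id Identifier of the source record.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, label, start_s, source_id = "record") {
  label <- match.arg(label, c("preictal", "interictal"))
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  structure(list(samples = samples, label = label,
                 start_s = as.numeric(start_s),
                 source_id = as.character(source_id)),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("eeg_segment: %s, %d channel(s) x %d samples, start %.6g s (%s)\n",
              x$label, nrow(x$samples), ncol(x$samples), x$start_s, x$source_id))
  invisible(x)
}
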