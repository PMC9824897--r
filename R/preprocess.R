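# Preprocessing: anti-aliased downsampling, 0-75 Hz zero-phase band-pass,
# and cutting non-overlapping labelled analysis windows.

zero_phase_lowpass <- function(x, cutoff_hz, rate, order = 4L) {
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Downsample an EEG record
#'
#' Applies an anti-alias zero-phase Butterworth low-pass (cut-off at 45% of
#' the target rate) before decimating. The source rate must be an integer
#' multiple of the target rate.
#'
#' @param record An [eeg_record()].
#' @param target_hz Target sampling rate, at most the record's rate.
#' @return The downsampled [eeg_record()]; duration preserved within one
#'   sample, annotations carried over unchanged.
#' @export
downsample <- function(record, target_hz) {
  validate_eeg_record(record)
  rate <- record$sampling_rate_hz
  if (target_hz > rate) stop("target_hz exceeds the record sampling rate")
  factor <- rate / target_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop("source rate must be an integer multiple of target_hz")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(record)
  keep <- seq(1L, ncol(record$samples), by = factor)
  out <- t(vapply(seq_len(nrow(record$samples)), function(ch) {
    zero_phase_lowpass(record$samples[ch, ], 0.45 * target_hz, rate)[keep]
  }, numeric(length(keep))))
  eeg_record(out, target_hz, record$channel_names, record$annotations)
}

#' Band-pass preprocess an EEG record
#'
#' Zero-phase (forward-backward) 4th-order Butterworth filter restricting
#' the record to `[low_hz, high_hz]`; with `low_hz = 0` the high-pass stage
#' is omitted and a pure low-pass is applied. Defaults implement the 0-75 Hz
#' preprocessing band.
#'
#' @param record An [eeg_record()].
#' @param low_hz Lower edge in Hz; `0` disables the high-pass stage.
#' @param high_hz Upper edge in Hz, strictly below Nyquist.
#' @param order Butterworth order per stage.
#' @return The filtered [eeg_record()].
#' @export
bandpass_preprocess <- function(record, low_hz = 0, high_hz = 75, order = 4L) {
  validate_eeg_record(record)
  nyq <- record$sampling_rate_hz / 2
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency")
  if (low_hz < 0 || low_hz >= high_hz) stop("need 0 <= low_hz < high_hz")
  w <- if (low_hz <= 0) high_hz / nyq else c(low_hz, high_hz) / nyq
  type <- if (low_hz <= 0) "low" else "pass"
  bf <- signal::butter(order, w, type = type)
  out <- t(apply(record$samples, 1, function(x) signal::filtfilt(bf, x)))
  eeg_record(out, record$sampling_rate_hz, record$channel_names,
             record$annotations)
}

#' Cut a record into non-overlapping labelled windows
#'
#' Windows are `[t, t + window_s)` starting at 0. A window is preictal iff
#' it lies fully inside a preictal horizon `[onset - preictal_horizon_s,
#' onset)`; windows overlapping any ictal span `[onset, offset)` are
#' discarded, as are windows overlapping the postictal guard
#' `[offset, offset + guard_s)`; every remaining window is interictal.
#'
#' @param record An [eeg_record()] with annotations.
#' @param window_s Window length in seconds; `window_s * rate` must be an
#'   integer.
#' @param preictal_horizon_s Length of the preictal period before each onset,
#'   seconds. Default 3600 (the lower bound of the 60-90 min preictal state).
#' @param guard_s Postictal guard after each offset, seconds. Default 1800.
#' @param source_id Identifier stored in each segment.
#' @return A list of [eeg_segment()] objects.
#' @export
segment_and_label <- function(record, window_s = 4,
                              preictal_horizon_s = 3600, guard_s = 1800,
                              source_id = "record") {
  validate_eeg_record(record)
  rate <- record$sampling_rate_hz
  wlen <- window_s * rate
  if (abs(wlen - round(wlen)) > 1e-9) stop("window_s * rate must be an integer")
  wlen <- as.integer(round(wlen))
  n <- ncol(record$samples)
  if (wlen > n) stop("window longer than the record")
  if (window_s <= 0) stop("window_s must be positive")
  if (preictal_horizon_s <= 0) stop("preictal_horizon_s must be positive")
  if (guard_s < 0) stop("guard_s must be nonnegative")
  ann <- record$annotations
  n_win <- n %/% wlen
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  segs <- vector("list", n_win)
  kept <- 0L
  for (i in seq_len(n_win)) {
    t0 <- (i - 1L) * window_s
    t1 <- t0 + window_s
    if (nrow(ann)) {
      if (any(overlaps(t0, t1, ann$onset_s, ann$offset_s))) next
      if (guard_s > 0 &&
          any(overlaps(t0, t1, ann$offset_s, ann$offset_s + guard_s))) next
      pre <- any(t0 >= ann$onset_s - preictal_horizon_s & t1 <= ann$onset_s)
    } else {
      pre <- FALSE
    }
    idx <- ((i - 1L) * wlen + 1L):(i * wlen)
    kept <- kept + 1L
    segs[[kept]] <- eeg_segment(record$samples[, idx, drop = FALSE],
                                if (pre) "preictal" else "interictal",
                                t0, source_id)
  }
  segs[seq_len(kept)]
}
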