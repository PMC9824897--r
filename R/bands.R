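# Decomposition of segments into the five classical EEG frequency bands.

#' Default EEG frequency band definitions
#'
#' delta 0-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-22 Hz and gamma
#' 22-30 Hz.
#'
#' @return Data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low_hz = c(0, 4, 8, 13, 22),
             high_hz = c(4, 8, 13, 22, 30),
             stringsAsFactors = FALSE)
}

#' Filter a segment into frequency bands
#'
#' Each band is extracted with a zero-phase 4th-order Butterworth band-pass
#' (a low-pass when the band's lower edge is 0, as for delta), so output
#' shapes equal the input shape and waveform morphology is preserved.
#'
#' @param segment An [eeg_segment()], or a channels x time numeric matrix.
#' @param sampling_rate_hz Sampling rate in Hz (required when `segment` is a
#'   bare matrix).
#' @param bands Band table as from [band_definitions()]; every `high_hz`
#'   must be below Nyquist.
#' @return A named list (one entry per band) of filtered channels x time
#'   matrices.
#' @export
decompose <- function(segment, sampling_rate_hz = NULL,
                      bands = band_definitions()) {
  if (inherits(segment, "eeg_segment")) {
    x <- segment$samples
  } else {
    x <- if (is.matrix(segment)) segment else matrix(segment, nrow = 1L)
  }
  if (is.null(sampling_rate_hz)) stop("sampling_rate_hz is required")
  nyq <- sampling_rate_hz / 2
  if (any(bands$high_hz >= nyq)) stop("band edge at or above Nyquist")
  if (any(bands$low_hz >= bands$high_hz)) stop("band low_hz must be below high_hz")
  out <- lapply(seq_len(nrow(bands)), function(b) {
    lo <- bands$low_hz[b]; hi <- bands$high_hz[b]
    w <- if (lo <= 0) hi / nyq else c(lo, hi) / nyq
    bf <- signal::butter(4, w, type = if (lo <= 0) "low" else "pass")
    t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
  })
  names(out) <- bands$name
  out
}
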