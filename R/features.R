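# Per-band, per-channel feature extraction: five statistical moments,
# wavelet energy/entropy, and histogram amplitude entropy. Entropies are in
# bits (base-2 logs).

#' Wavelet feature configuration
#'
#' @param wavelet Wavelet family; only `"db4"` is implemented.
#' @param level Decomposition depth, default 5 (so the deepest approximation
#'   band covers 0-4 Hz at 256 Hz sampling).
#' @param per_subband If `TRUE`, [extract_features()] emits one relative
#'   energy per sub-band instead of the scalar summary.
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(wavelet = "db4", level = 5L, per_subband = FALSE) {
  wavelet <- match.arg(wavelet, "db4")
  if (level < 1L) stop("level must be at least 1")
  structure(list(wavelet = wavelet, level = as.integer(level),
                 per_subband = isTRUE(per_subband)),
            class = "wavelet_config")
}

#' Statistical features of a sample sequence
#'
#' Mean, unbiased variance, standard deviation, and the moment-ratio
#' skewness and kurtosis \eqn{\sum (A_r - \bar A)^3 / (q d^3)} and
#' \eqn{\sum (A_r - \bar A)^4 / (q d^4)} with `d` the sample standard
#' deviation (kurtosis is not excess-corrected). A constant input has zero
#' standard deviation, in which case skewness and kurtosis are 0 by
#' convention and a warning is raised.
#'
#' @param x Numeric vector with at least 2 values.
#' @return Named numeric vector `FMN`, `FVR`, `FSDN`, `FSKW`, `FKRT`.
#' @export
statistical_features <- function(x) {
  q <- length(x)
  if (q < 2) stop("need at least 2 samples")
  fmn <- sum(x) / q
  dev <- x - fmn
  fvr <- sum(dev^2) / (q - 1)
  fsdn <- sqrt(fvr)
  if (fsdn == 0) {
    warning("zero standard deviation; skewness and kurtosis set to 0")
    fskw <- 0
    fkrt <- 0
  } else {
    fskw <- sum(dev^3) / (q * fsdn^3)
    fkrt <- sum(dev^4) / (q * fsdn^4)
  }
  c(FMN = fmn, FVR = fvr, FSDN = fsdn, FSKW = fskw, FKRT = fkrt)
}

#' Wavelet energy and entropy features
#'
#' Decomposes `x` with the periodized db4 DWT, computes each sub-band's
#' energy \eqn{B(w) = \sum_r |S_w[r]|^2}, the relative energies
#' \eqn{B(w) / \sum B}, and their Shannon entropy in bits. A zero-energy
#' input yields all-zero relative energies and zero entropy by convention,
#' with a warning.
#'
#' @param x Numeric sample sequence.
#' @param cfg A [wavelet_config()].
#' @return List with `FWEY` (named relative energy per sub-band, ordered
#'   `a<level>`, `d<level>`, ..., `d1`) and `FWEN` (wavelet entropy, bits).
#' @export
wavelet_features <- function(x, cfg = wavelet_config()) {
  coefs <- dwt_db4(x, cfg$level)
  energies <- vapply(coefs, function(cc) sum(cc^2), 0)
  total <- sum(energies)
  if (total <= 0) {
    warning("zero total wavelet energy; relative energies and entropy set to 0")
    fwey <- energies * 0
    fwen <- 0
  } else {
    fwey <- energies / total
    nz <- fwey > 0
    fwen <- -sum(fwey[nz] * log2(fwey[nz]))
  }
  list(FWEY = fwey, FWEN = fwen)
}

#' Histogram amplitude entropy
#'
#' Discretizes the amplitudes into `n_bins` equal-width bins spanning
#' `[min(x), max(x)]` and returns the Shannon entropy of the bin relative
#' frequencies, in bits. A constant input falls in a single bin and has
#' entropy 0.
#'
#' @param x Non-empty numeric vector.
#' @param n_bins Number of histogram bins (>= 1), default 16.
#' @return The entropy `FHEN` in `[0, log2(n_bins)]`.
#' @export
entropy_feature <- function(x, n_bins = 16L) {
  if (length(x) == 0) stop("empty input")
  if (n_bins < 1) stop("n_bins must be at least 1")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  bin <- pmin(as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins)) + 1L,
              as.integer(n_bins))
  p <- tabulate(bin, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the full feature vector from band-decomposed signals
#'
#' For every (band, channel) pair computes the five statistical features,
#' a scalar relative wavelet energy `FWEY` (total detail-band relative
#' energy, i.e. 1 minus the approximation band's share; per-sub-band values
#' via `cfg$per_subband`), the wavelet entropy `FWEN` and the amplitude
#' entropy `FHEN`. Names follow `<band>.<channel>.<feature>`, ordered
#' band-major, then channel, then the feature order `FMN, FVR, FSDN, FSKW,
#' FKRT, FWEY, FWEN, FHEN`.
#'
#' @param band_signals Named list of channels x time matrices as returned by
#'   [decompose()].
#' @param cfg A [wavelet_config()].
#' @param n_bins Histogram bins for [entropy_feature()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(band_signals, cfg = wavelet_config(),
                             n_bins = 16L) {
  vals <- numeric(0)
  nms <- character(0)
  for (band in names(band_signals)) {
    mat <- band_signals[[band]]
    for (ch in seq_len(nrow(mat))) {
      x <- mat[ch, ]
      stat <- statistical_features(x)
      wv <- wavelet_features(x, cfg)
      if (cfg$per_subband) {
        wey <- wv$FWEY
        wey_names <- paste0("FWEY.", names(wey))
      } else {
        wey <- 1 - wv$FWEY[[paste0("a", cfg$level)]]
        wey_names <- "FWEY"
      }
      hen <- entropy_feature(x, n_bins)
      vals <- c(vals, stat, wey, wv$FWEN, hen)
      nms <- c(nms, paste0(band, ".ch", ch, ".",
                           c(names(stat), wey_names, "FWEN", "FHEN")))
    }
  }
  names(vals) <- nms
  if (!all(is.finite(vals))) stop("non-finite feature value produced")
  vals
}

#' Feature matrix from a list of labelled segments
#'
#' Runs [decompose()] and [extract_features()] on every segment and stacks
#' the results.
#'
#' @param segments List of [eeg_segment()] objects.
#' @param sampling_rate_hz Sampling rate of the segments.
#' @param bands Band table, default [band_definitions()].
#' @param cfg A [wavelet_config()].
#' @param n_bins Histogram bins for the amplitude entropy.
#' @return List with `X` (segments x features matrix), `y` (integer labels,
#'   preictal = 1), and `meta` (data frame with `source_id`, `start_s`,
#'   `label`).
#' @export
segments_to_features <- function(segments, sampling_rate_hz,
                                 bands = band_definitions(),
                                 cfg = wavelet_config(), n_bins = 16L) {
  if (!length(segments)) stop("no segments supplied")
  rows <- lapply(segments, function(seg) {
    extract_features(decompose(seg, sampling_rate_hz, bands), cfg, n_bins)
  })
  X <- do.call(rbind, rows)
  y <- vapply(segments, function(s) as.integer(s$label == "preictal"), 0L)
  meta <- data.frame(
    source_id = vapply(segments, function(s) s$source_id, ""),
    start_s = vapply(segments, function(s) s$start_s, 0),
    label = vapply(segments, function(s) s$label, ""))
  list(X = X, y = y, meta = meta)
}
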