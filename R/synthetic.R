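# Seeded synthetic EEG and tabular feature generators. These define the
# study conditions every downstream stage is tested under, so that no
# external recordings are needed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic sub-seed stream: small-integer-safe 32-bit mixing
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807 + 12345) %%
               2147483647)
}

#' Configuration for the synthetic EEG record generator
#'
#' @param sampling_rate_hz Sampling rate, default 256 Hz.
#' @param duration_s Record duration, seconds.
#' @param n_channels Number of channels.
#' @param seizure_times List of `c(onset_s, offset_s)` pairs, disjoint and
#'   within the record.
#' @param preictal_horizon_s Length of the preictal span before each onset
#'   over which the preictal signature is applied, seconds.
#' @param preictal_delta_gain Amplitude multiplier (>= 1) on the delta and
#'   theta rhythms inside each preictal horizon.
#' @param spike_burst_rate_hz Repetition rate of the spike-wave bursts added
#'   in preictal and ictal spans, default 3 Hz.
#' @param noise_exponent Spectral exponent beta of the 1/f^beta background.
#' @param seed Integer seed; the generator is a pure function of the config.
#' @return A `synth_record_config` list.
#' @export
synth_record_config <- function(sampling_rate_hz = 256, duration_s = 600,
                                n_channels = 2, seizure_times = list(),
                                preictal_horizon_s = 600,
                                preictal_delta_gain = 3,
                                spike_burst_rate_hz = 3,
                                noise_exponent = 1, seed = 1L) {
  cfg <- list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
              n_channels = n_channels, seizure_times = seizure_times,
              preictal_horizon_s = preictal_horizon_s,
              preictal_delta_gain = preictal_delta_gain,
              spike_burst_rate_hz = spike_burst_rate_hz,
              noise_exponent = noise_exponent, seed = as.integer(seed))
  if (duration_s <= 0) stop("duration_s must be positive")
  if (n_channels < 1) stop("n_channels must be at least 1")
  if (preictal_delta_gain < 1) stop("preictal_delta_gain must be >= 1")
  if (length(seizure_times)) {
    iv <- do.call(rbind, lapply(seizure_times, as.numeric))
    if (any(iv[, 1] < 0 | iv[, 1] >= iv[, 2] | iv[, 2] > duration_s)) {
      stop("seizure intervals must be within [0, duration_s] with onset < offset")
    }
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("seizure intervals must be disjoint")
    }
  }
  structure(cfg, class = "synth_record_config")
}

one_over_f_noise <- function(n, beta) {
  # spectral shaping of white Gaussian noise: |X(f)| ~ f^(-beta/2)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))            # avoid f = 0 blow-up at DC
  f <- pmin(f, n - f + 1)              # mirrored frequency index
  X <- X * f^(-beta / 2)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

spike_wave_burst <- function(t_local, rate_hz) {
  # biphasic sawtooth spike-wave surrogate at rate_hz
  ph <- (t_local * rate_hz) %% 1
  sharp <- ifelse(ph < 0.2, ph / 0.2, pmax(0, 1 - (ph - 0.2) / 0.3))
  2 * sharp - 0.5
}

#' Generate a synthetic EEG record with planted seizure structure
#'
#' The record is the sum of one band-limited sinusoid per classical EEG band
#' (delta 2 Hz, theta 6 Hz, alpha 10.5 Hz, beta 17.5 Hz, gamma 26 Hz, with
#' amplitudes decreasing with frequency) plus 1/f^beta Gaussian background
#' noise. Inside each preictal horizon the delta and theta components are
#' scaled by `preictal_delta_gain` and 3 Hz spike-wave bursts of 1-2 s are
#' added; bursts are also present during ictal spans. Annotations carry the
#' configured seizure intervals.
#'
#' @param config A [synth_record_config()].
#' @return An [eeg_record()]; identical for identical configs (seed included).
#' @export
generate_record <- function(config) {
  if (!inherits(config, "synth_record_config")) {
    stop("config must be a synth_record_config")
  }
  rate <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * rate))
  t <- (seq_len(n) - 1L) / rate
  freqs <- c(delta = 2, theta = 6, alpha = 10.5, beta = 17.5, gamma = 26)
  amps <- c(delta = 20, theta = 10, alpha = 8, beta = 5, gamma = 3)
  slow <- c(TRUE, TRUE, FALSE, FALSE, FALSE)

  gain <- rep(1, n)
  burst_mask <- rep(FALSE, n)
  iv <- if (length(config$seizure_times)) {
    do.call(rbind, lapply(config$seizure_times, as.numeric))
  } else matrix(0, 0, 2)

  with_seed(config$seed, {
    for (r in seq_len(nrow(iv))) {
      pre0 <- max(0, iv[r, 1] - config$preictal_horizon_s)
      pre_idx <- t >= pre0 & t < iv[r, 1]
      gain[pre_idx] <- config$preictal_delta_gain
      # spike-wave bursts of 1-2 s sprinkled over preictal and ictal spans
      for (span in list(c(pre0, iv[r, 1]), c(iv[r, 1], iv[r, 2]))) {
        len <- span[2] - span[1]
        n_burst <- max(1L, as.integer(floor(len / 10)))
        starts <- span[1] + stats::runif(n_burst, 0, max(0, len - 2))
        durs <- stats::runif(n_burst, 1, 2)
        for (b in seq_len(n_burst)) {
          burst_mask <- burst_mask |
            (t >= starts[b] & t < pmin(starts[b] + durs[b], span[2]))
        }
      }
    }
    samples <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      x <- numeric(n)
      for (b in seq_along(freqs)) {
        phase <- stats::runif(1, 0, 2 * pi)
        comp <- amps[b] * sin(2 * pi * freqs[b] * t + phase)
        if (slow[b]) comp <- comp * gain
        x <- x + comp
      }
      x[burst_mask] <- x[burst_mask] +
        30 * spike_wave_burst(t[burst_mask], config$spike_burst_rate_hz)
      x <- x + 5 * one_over_f_noise(n, config$noise_exponent)
      samples[ch, ] <- x
    }
    ann <- if (nrow(iv)) data.frame(onset_s = iv[, 1], offset_s = iv[, 2]) else NULL
    eeg_record(samples, rate, paste0("synth", seq_len(config$n_channels)), ann)
  })
}

#' Configuration for the synthetic tabular feature generator
#'
#' @param n_samples Number of rows (>= 4).
#' @param n_features Total feature count D.
#' @param n_informative Number k of informative features (0 < k <= D).
#' @param effect_size Mean shift between classes on informative features, in
#'   units of the within-class standard deviation.
#' @param class_balance Fraction of class-1 rows, default 0.5.
#' @param seed Integer seed.
#' @return A `synth_feature_config` list.
#' @export
synth_feature_config <- function(n_samples = 400, n_features = 40,
                                 n_informative = 5, effect_size = 3,
                                 class_balance = 0.5, seed = 1L) {
  if (n_samples < 4) stop("n_samples must be at least 4")
  if (n_informative <= 0 || n_informative > n_features) {
    stop("need 0 < n_informative <= n_features")
  }
  if (class_balance <= 0 || class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, effect_size = effect_size,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "synth_feature_config")
}

#' Generate a labelled feature dataset with planted informative columns
#'
#' Informative columns are standard normal within class with class means
#' `-effect_size/2` and `+effect_size/2`; the remaining columns are
#' class-independent standard normal noise. The ground-truth informative
#' index set is returned for recovery tests.
#'
#' @param config A [synth_feature_config()].
#' @return A list with `X` (n x D numeric matrix with column names
#'   `f1..fD`), `y` (integer labels in `{0, 1}`), and `informative`
#'   (sorted indices of the informative columns).
#' @export
generate_feature_dataset <- function(config) {
  if (!inherits(config, "synth_feature_config")) {
    stop("config must be a synth_feature_config")
  }
  with_seed(config$seed, {
    n <- config$n_samples
    D <- config$n_features
    k <- config$n_informative
    n1 <- as.integer(round(n * config$class_balance))
    y <- c(rep(1L, n1), rep(0L, n - n1))
    X <- matrix(stats::rnorm(n * D), n, D)
    informative <- sort(sample.int(D, k))
    shift <- config$effect_size / 2
    X[, informative] <- X[, informative] + ifelse(y == 1L, shift, -shift)
    colnames(X) <- paste0("f", seq_len(D))
    list(X = X, y = y, informative = informative)
  })
}

#' Write a feature dataset to CSV
#'
#' @param dataset A list with `X` and `y` as returned by
#'   [generate_feature_dataset()].
#' @param path Output CSV path; features plus a final `label` column.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(dataset, path) {
  df <- as.data.frame(dataset$X)
  df$label <- dataset$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature dataset from CSV
#'
#' @param path CSV with feature columns and a `label` column.
#' @return A list with `X` and `y`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"label" %in% names(df)) stop("feature CSV must have a 'label' column")
  y <- as.integer(df$label)
  X <- as.matrix(df[, setdiff(names(df), c("label", "source_id", "start_s")),
                    drop = FALSE])
  list(X = X, y = y)
}
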