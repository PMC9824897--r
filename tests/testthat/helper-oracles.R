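# Independent brute-force oracles used to cross-check the implementation.

# Moment formulas evaluated element-by-element in a plain loop.
oracle_moments <- function(x) {
  q <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mn <- s / q
  s2 <- s3 <- s4 <- 0
  for (v in x) {
    s2 <- s2 + (v - mn)^2
    s3 <- s3 + (v - mn)^3
    s4 <- s4 + (v - mn)^4
  }
  vr <- s2 / (q - 1)
  d <- sqrt(vr)
  c(FMN = mn, FVR = vr, FSDN = d,
    FSKW = if (d > 0) s3 / (q * d^3) else 0,
    FKRT = if (d > 0) s4 / (q * d^4) else 0)
}

oracle_confusion <- function(pred, truth) {
  tp <- tn <- rp <- rn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1) rp <- rp + 1 else rn <- rn + 1
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
  }
  c(acc = (tp + tn) / (rp + rn), sens = tp / rp, spec = tn / rn)
}

# dominant FFT frequency of a real signal, in Hz
fft_peak_hz <- function(x, rate) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  spec[1] <- 0   # ignore DC
  (which.max(spec) - 1) * rate / n
}

# band power from the periodogram, in [lo, hi) Hz
fft_band_power <- function(x, rate, lo, hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * rate / n
  sum(spec[f >= lo & f < hi])
}

rms <- function(x) sqrt(mean(x^2))

# exhaustive best stump accuracy (unweighted), for the boosting ceiling
oracle_best_stump_accuracy <- function(X, y_pm) {
  best <- 0
  for (j in seq_len(ncol(X))) {
    for (thr in unique(c(X[, j] - 1e-9, max(X[, j]) + 1))) {
      for (p in c(1, -1)) {
        pred <- ifelse(X[, j] > thr, 1, -1) * p
        best <- max(best, mean(pred == y_pm))
      }
    }
  }
  best
}

# exhaustive best first split by Gini impurity decrease
oracle_best_first_split <- function(X, y) {
  n <- length(y)
  gini <- function(yy) {
    if (!length(yy)) return(0)
    p <- mean(yy)
    1 - p^2 - (1 - p)^2
  }
  parent <- gini(y)
  best <- -Inf
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      thr <- (xs[i] + xs[i + 1]) / 2
      left <- X[, j] <= thr
      gain <- parent - (sum(left) * gini(y[left]) +
                          sum(!left) * gini(y[!left])) / n
      best <- max(best, gain)
    }
  }
  best
}

make_toy_record <- function(duration_s = 10, rate = 256, n_channels = 1,
                            seizures = NULL, seed = 1) {
  set.seed(seed)
  n <- duration_s * rate
  samples <- matrix(rnorm(n_channels * n), n_channels, n)
  ann <- if (is.null(seizures)) NULL else {
    data.frame(onset_s = vapply(seizures, `[`, 0, 1),
               offset_s = vapply(seizures, `[`, 0, 2))
  }
  eeg_record(samples, rate, annotations = ann)
}
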