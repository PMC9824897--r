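test_that("statistical features match hand-computed values", {
  expect_warning(f <- statistical_features(c(5, 5, 5, 5)), "zero standard")
  expect_equal(unname(f), c(5, 0, 0, 0, 0))

  sym <- c(-3, -2, -1, -0.5, 0.5, 1, 2, 3)
  expect_equal(statistical_features(sym)[["FSKW"]], 0)

  f <- statistical_features(c(-1, 1, -1, 1))
  expect_equal(f[["FKRT"]], 0.5625)

  f <- statistical_features(c(1, 2, 3, 4))
  expect_equal(f[["FMN"]], 2.5)
  expect_equal(f[["FVR"]], 5 / 3)
  expect_equal(f[["FSDN"]], sqrt(5 / 3))

  expect_error(statistical_features(3), "2 samples")
})

test_that("statistical features agree with a brute-force oracle on 1000 inputs", {
  set.seed(77)
  for (i in 1:1000) {
    x <- rnorm(sample(4:50, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 4))
    got <- statistical_features(x)
    want <- oracle_moments(x)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("db4 DWT matches the reference decomposition and conserves energy", {
  # frozen reference: PyWavelets wavedec(db4, periodization, level 5) on
  # sin(2*pi*5*t) + 0.5*cos(2*pi*40*t), t = 0..255/256
  t <- (0:255) / 256
  x <- sin(2 * pi * 5 * t) + 0.5 * cos(2 * pi * 40 * t)
  wf <- wavelet_features(x, wavelet_config(level = 5))
  expect_equal(unname(wf$FWEY),
               c(0.104741306097, 0.656896737225, 0.038357085154,
                 0.026198512944, 0.164262213077, 0.009544145502),
               tolerance = 1e-9)
  expect_equal(wf$FWEN, 1.549404518198, tolerance = 1e-9)

  # orthonormal transform: sub-band energies partition signal energy
  set.seed(5)
  for (i in 1:20) {
    z <- rnorm(256)
    coefs <- dwt_db4(z, 5)
    expect_equal(sum(vapply(coefs, function(cc) sum(cc^2), 0)), sum(z^2),
                 tolerance = 1e-9)
  }
})

test_that("wavelet feature conventions hold at the boundaries", {
  expect_warning(wz <- wavelet_features(numeric(64)), "zero total")
  expect_true(all(wz$FWEY == 0))
  expect_equal(wz$FWEN, 0)

  set.seed(2)
  for (i in 1:20) {
    w <- wavelet_features(rnorm(128), wavelet_config(level = 4))
    expect_true(all(w$FWEY >= 0))
    expect_equal(sum(w$FWEY), 1, tolerance = 1e-12)
    expect_gte(w$FWEN, 0)
    expect_lte(w$FWEN, log2(length(w$FWEY)))
  }

  # slow tone concentrates in the deepest approximation band
  t <- (0:1023) / 256
  slow <- sin(2 * pi * 2 * t)
  w <- wavelet_features(slow, wavelet_config(level = 5))
  expect_equal(names(which.max(w$FWEY)), "a5")

  expect_error(dwt_db4(rnorm(16), 5), "too short")
})

test_that("histogram entropy matches direct Shannon sums", {
  expect_equal(entropy_feature(c(0, 0, 1, 1), n_bins = 2), 1)
  expect_equal(entropy_feature(rep(3.7, 50), n_bins = 8), 0)
  # frequencies (0.5, 0.25, 0.25, 0) over 4 bins -> 1.5 bits
  expect_equal(entropy_feature(c(0, 0, 1.2, 2.1), n_bins = 4), 1.5)
  expect_error(entropy_feature(numeric(0)), "empty")
  set.seed(3)
  for (i in 1:20) {
    h <- entropy_feature(rnorm(200), n_bins = 16)
    expect_gte(h, 0)
    expect_lte(h, 4)
  }
})

test_that("extract_features emits the documented vector layout deterministically", {
  set.seed(8)
  seg <- matrix(rnorm(2 * 1024), 2)
  bs <- decompose(seg, 256)
  v1 <- extract_features(bs)
  v2 <- extract_features(bs)
  expect_identical(v1, v2)
  expect_length(v1, 80)  # 5 bands x 2 channels x 8 features
  expect_equal(names(v1)[1:8],
               paste0("delta.ch1.",
                      c("FMN", "FVR", "FSDN", "FSKW", "FKRT", "FWEY",
                        "FWEN", "FHEN")))
  expect_equal(names(v1)[9], "delta.ch2.FMN")
  expect_equal(names(v1)[65], "gamma.ch1.FMN")
  expect_true(all(is.finite(v1)))
})

test_that("relative-energy features are scale invariant, variance scales quadratically", {
  set.seed(9)
  seg <- matrix(rnorm(1024), 1)
  b1 <- decompose(seg, 256)
  b10 <- decompose(seg * 10, 256)
  v1 <- extract_features(b1)
  v10 <- extract_features(b10)
  for (band in band_definitions()$name) {
    pick <- function(v, f) v[[paste0(band, ".ch1.", f)]]
    expect_equal(pick(v10, "FWEY"), pick(v1, "FWEY"), tolerance = 1e-6)
    expect_equal(pick(v10, "FWEN"), pick(v1, "FWEN"), tolerance = 1e-6)
    expect_equal(pick(v10, "FHEN"), pick(v1, "FHEN"), tolerance = 1e-6)
    expect_equal(pick(v10, "FVR"), 100 * pick(v1, "FVR"), tolerance = 1e-6)
  }
})
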