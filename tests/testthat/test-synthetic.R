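test_that("record generation is a pure function of the config", {
  cfg <- synth_record_config(duration_s = 20, n_channels = 3,
                             seizure_times = list(c(12, 15)),
                             preictal_horizon_s = 8, seed = 42)
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$annotations, b$annotations)

  cfg2 <- synth_record_config(duration_s = 60, n_channels = 4, seed = 5)
  rec <- generate_record(cfg2)
  expect_equal(dim(rec$samples), c(4, 15360))
  expect_no_error(validate_eeg_record(rec))
})

test_that("preictal windows carry elevated delta-band relative energy", {
  cfg <- synth_record_config(duration_s = 300, n_channels = 1,
                             seizure_times = list(c(240, 270)),
                             preictal_horizon_s = 120,
                             preictal_delta_gain = 3, seed = 11)
  rec <- generate_record(cfg)
  segs <- segment_and_label(rec, window_s = 4, preictal_horizon_s = 120,
                            guard_s = 10)
  rel_delta <- vapply(segs, function(s) {
    x <- s$samples[1, ]
    fft_band_power(x, 256, 0, 4) / fft_band_power(x, 256, 0, 128)
  }, 0)
  lab <- vapply(segs, function(s) s$label, "")
  expect_gt(mean(rel_delta[lab == "preictal"]),
            mean(rel_delta[lab == "interictal"]))
})

test_that("seizure interval validation rejects bad configs", {
  expect_error(synth_record_config(duration_s = 10,
                                   seizure_times = list(c(8, 12))), "within")
  expect_error(synth_record_config(duration_s = 30,
                                   seizure_times = list(c(2, 10), c(5, 12))),
               "disjoint")
  expect_error(synth_feature_config(n_features = 10, n_informative = 11),
               "n_informative")
})

test_that("null feature datasets show no systematic class separation", {
  sig_cols <- integer(100)
  for (s in 1:100) {
    d <- generate_feature_dataset(
      synth_feature_config(n_samples = 100, n_features = 20,
                           n_informative = 1, effect_size = 0, seed = s))
    p <- vapply(seq_len(ncol(d$X)), function(j) {
      stats::t.test(d$X[d$y == 1, j], d$X[d$y == 0, j])$p.value
    }, 0)
    sig_cols[s] <- sum(p < 0.01)
  }
  # at alpha = 0.01 and 20 columns, nearly every seed has no or one false hit
  expect_gte(sum(sig_cols <= 2), 95)
})

test_that("planted signal at effect size 3 is learnable by a shallow tree", {
  d <- generate_feature_dataset(synth_feature_config(400, 40, 5, 3, seed = 2))
  tr <- rep(c(TRUE, FALSE), length.out = 400)
  tree <- dt_train(d$X[tr, ], d$y[tr], max_depth = 3)
  acc <- mean(predict(tree, d$X[!tr, ], type = "label") == d$y[!tr])
  expect_gte(acc, 0.9)

  bal <- generate_feature_dataset(
    synth_feature_config(n_samples = 100, n_features = 5, n_informative = 2,
                         class_balance = 0.5, seed = 3))
  expect_equal(sum(bal$y == 1), 50)
  expect_equal(sum(bal$y == 0), 50)
})

test_that("feature CSV round-trips", {
  d <- generate_feature_dataset(synth_feature_config(20, 4, 2, 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(d, path)
  back <- read_feature_csv(path)
  expect_equal(back$X, d$X, tolerance = 1e-12)
  expect_equal(back$y, d$y)
})
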