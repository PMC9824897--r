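# Orchestration: wrapper feature selection and fusion-weight tuning driven
# by the hybrid seek optimizer, the accuracy/sensitivity/specificity
# metrics, the training-percentage and k-fold protocols, and the
# record-to-report end-to-end run.

#' Pipeline configuration
#'
#' Collects every stage's tunables and the evaluation protocol. Exactly one
#' protocol is active: `protocol = "trainpct"` with `train_percentages`, or
#' `protocol = "kfold"` with `k_values`.
#'
#' @param downsample_hz Optional target rate for [downsample()]; `NULL`
#'   keeps the native rate.
#' @param bandpass_low_hz,bandpass_high_hz Preprocessing band, default
#'   0-75 Hz.
#' @param window_s Analysis window length, seconds (default 4).
#' @param preictal_horizon_s,guard_s Labelling horizon and postictal guard
#'   passed to [segment_and_label()].
#' @param wavelet A [wavelet_config()].
#' @param n_bins Histogram bins for the amplitude entropy.
#' @param select_population,select_iterations Optimizer budget for feature
#'   selection.
#' @param surrogate_rounds Boosting rounds of the stump surrogate scoring
#'   candidate masks during selection, default 8.
#' @param fusion_population,fusion_iterations Optimizer budget for fusion
#'   weight tuning.
#' @param adaboost_rounds,rf_trees Base-model sizes.
#' @param dt_max_depth Depth of the standalone decision tree.
#' @param select_features Logical; run wrapper feature selection (default
#'   `TRUE`).
#' @param protocol `"trainpct"` or `"kfold"`, or `NULL` (must be set before
#'   [run_protocol()]).
#' @param train_percentages Training percentages evaluated under
#'   `"trainpct"`; default `c(40, 50, 60, 80, 90)`.
#' @param k_values Fold counts evaluated under `"kfold"`; default
#'   `c(2, 4, 6, 8, 10, 12)`.
#' @param seed Global seed; every stage derives its own sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(downsample_hz = NULL,
                            bandpass_low_hz = 0, bandpass_high_hz = 75,
                            window_s = 4, preictal_horizon_s = 3600,
                            guard_s = 1800,
                            wavelet = wavelet_config(), n_bins = 16L,
                            select_population = 20L, select_iterations = 40L,
                            surrogate_rounds = 8L,
                            fusion_population = 15L, fusion_iterations = 30L,
                            adaboost_rounds = 20L, rf_trees = 50L,
                            dt_max_depth = 8L, select_features = TRUE,
                            protocol = NULL,
                            train_percentages = c(40, 50, 60, 80, 90),
                            k_values = c(2, 4, 6, 8, 10, 12),
                            seed = 1L) {
  if (!is.null(protocol)) {
    protocol <- match.arg(protocol, c("trainpct", "kfold"))
  }
  structure(list(downsample_hz = downsample_hz,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 window_s = window_s,
                 preictal_horizon_s = preictal_horizon_s, guard_s = guard_s,
                 wavelet = wavelet, n_bins = n_bins,
                 select_population = select_population,
                 select_iterations = select_iterations,
                 surrogate_rounds = as.integer(surrogate_rounds),
                 fusion_population = fusion_population,
                 fusion_iterations = fusion_iterations,
                 adaboost_rounds = adaboost_rounds, rf_trees = rf_trees,
                 dt_max_depth = dt_max_depth,
                 select_features = isTRUE(select_features),
                 protocol = protocol,
                 train_percentages = train_percentages, k_values = k_values,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

stratified_split <- function(y, train_frac, seed) {
  with_seed(seed, {
    train <- logical(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      n_tr <- round(train_frac * length(idx))
      train[idx[seq_len(n_tr)]] <- TRUE
    }
    train
  })
}

# Fast wrapper-selection surrogate: boosted decision stumps evaluated by
# stratified 3-fold CV. Column sort orders, sorted values, valid cut points
# and candidate thresholds are precomputed once per fold, so each fitness
# evaluation only runs cumulative sums over the masked columns. Boosted
# stumps are additive in the features, so the surrogate rewards every
# informative feature a mask includes (a greedy tree saturates after a few).
make_boost_surrogate <- function(X, y, fold, rounds = 8L) {
  k <- max(fold)
  y_pm <- ifelse(y == 1L, 1, -1)
  pre <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f)
    va <- which(fold == f)
    n_tr <- length(tr)
    cols <- lapply(seq_len(ncol(X)), function(j) {
      o <- order(X[tr, j], method = "radix")
      xs <- X[tr[o], j]
      valid <- c(xs[-n_tr] != xs[-1], TRUE)
      thr <- c(xs[1] - 1, ((xs + c(xs[-1], xs[n_tr] + 2)) / 2)[valid])
      list(ord = o, xs = xs, valid = valid, thr = thr)
    })
    list(tr = tr, va = va, n_tr = n_tr, cols = cols)
  })
  fit_fold <- function(p, mask_idx) {
    n_tr <- p$n_tr
    ytr <- y_pm[p$tr]
    w <- rep(1 / n_tr, n_tr)
    margin_va <- numeric(length(p$va))
    for (r in seq_len(rounds)) {
      best <- list(err = Inf)
      for (j in mask_idx) {
        cj <- p$cols[[j]]
        wy <- (w * ytr)[cj$ord]
        pos <- pmax(wy, 0)
        cum_pos <- cumsum(pos)
        tot_neg <- cum_pos[n_tr] - sum(wy)      # total weight of -1 labels
        cum_neg <- cum_pos - cumsum(wy)
        err_plus <- c(tot_neg, (cum_pos + tot_neg - cum_neg)[cj$valid])
        i1 <- which.min(err_plus)
        i2 <- which.max(err_plus)
        if (err_plus[i1] < best$err - 1e-12) {
          best <- list(feature = j, threshold = cj$thr[i1], polarity = 1,
                       err = err_plus[i1])
        }
        if (1 - err_plus[i2] < best$err - 1e-12) {
          best <- list(feature = j, threshold = cj$thr[i2], polarity = -1,
                       err = 1 - err_plus[i2])
        }
      }
      if (!is.finite(best$err) || best$err >= 0.5) break
      tau <- learner_weight(best$err)
      pred_tr <- ifelse(X[p$tr, best$feature] > best$threshold, 1, -1) *
        best$polarity
      margin_va <- margin_va + tau * best$polarity *
        ifelse(X[p$va, best$feature] > best$threshold, 1, -1)
      w <- w * exp(-tau * ytr * pred_tr)
      w <- w / sum(w)
      if (best$err <= 0) break
    }
    mean((margin_va >= 0) == (y_pm[p$va] > 0))
  }
  function(mask) {
    mask_idx <- which(mask)
    mean(vapply(pre, fit_fold, 0, mask_idx = mask_idx))
  }
}

#' Position-to-mask thresholding
#'
#' A feature is included iff its coordinate is at least 0.5.
#'
#' @param position Numeric vector in `[0, 1]^D`.
#' @return Logical inclusion mask.
#' @export
position_to_mask <- function(position) position >= 0.5

#' Wrapper feature selection with the hybrid seek optimizer
#'
#' Searches `[0, 1]^D`; each position is thresholded at 0.5 into a mask and
#' scored by the mean stratified 3-fold validation accuracy of a boosted
#' decision-stump classifier trained on the masked columns (a cheap
#' surrogate for the full ensemble whose additive form rewards every
#' informative feature a mask retains). Empty masks receive a fitness below
#' any attainable accuracy, so the returned mask is never empty.
#'
#' @param X Feature matrix with at least 2 columns.
#' @param y Labels in `{0, 1}`, both classes present.
#' @param config A [pipeline_config()] supplying the optimizer budget and
#'   seed.
#' @return List with `mask` (logical), `position`, `fitness` (surrogate CV
#'   accuracy of the selected mask), and the optimizer `history`.
#' @export
select_features <- function(X, y, config = pipeline_config()) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 features")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  fold <- stratified_folds(y, 3L, derive_seed(config$seed, 101L))
  surrogate <- make_boost_surrogate(X, y, fold,
                                    rounds = config$surrogate_rounds)
  fitness <- function(pos) {
    mask <- position_to_mask(pos)
    if (!any(mask)) return(-1)   # below any accuracy: empty masks never win
    surrogate(mask)
  }
  opt_cfg <- hybrid_seek_config(
    population_size = config$select_population,
    max_iterations = config$select_iterations,
    bounds = c(0, 1), seed = derive_seed(config$seed, 102L))
  res <- hs_optimize(fitness, ncol(X), opt_cfg)
  mask <- position_to_mask(res$best_position)
  if (!any(mask)) mask[which.max(res$best_position)] <- TRUE
  list(mask = mask, position = res$best_position,
       fitness = res$best_fitness, history = res$history)
}

#' Project raw optimizer output onto the weight simplex
#'
#' Floors each coordinate at 1e-6 and divides by the sum, so the result is
#' strictly positive and sums to 1 exactly.
#'
#' @param w Length-3 nonnegative vector.
#' @return Simplex weights.
#' @export
project_simplex <- function(w) {
  w <- pmax(as.numeric(w), 1e-6)
  w / sum(w)
}

#' Tune the fusion weights on a validation set
#'
#' Runs the hybrid seek optimizer over `[0, 1]^3`; every candidate is
#' projected onto the simplex by [project_simplex()] before evaluation, and
#' the fitness is the fused validation accuracy. If all three base models
#' produce constant scores on the validation set the weights are
#' uninformative and `(1/3, 1/3, 1/3)` is returned with a warning.
#'
#' @param adaboost,forest,tree Trained base models.
#' @param X_val,y_val Validation set containing both classes.
#' @param config A [pipeline_config()].
#' @return Numeric `(tau, rho, eps)` summing to 1.
#' @export
tune_fusion_weights <- function(adaboost, forest, tree, X_val, y_val,
                                config = pipeline_config()) {
  if (length(unique(y_val)) < 2) stop("validation labels contain a single class")
  base <- cbind(predict(adaboost, X_val, type = "score"),
                predict(forest, X_val, type = "score"),
                predict(tree, X_val, type = "score"))
  if (all(apply(base, 2, function(s) max(s) - min(s)) < 1e-12)) {
    warning("all base models are constant on the validation set; using equal weights")
    return(rep(1 / 3, 3))
  }
  fitness <- function(pos) {
    w <- project_simplex(pos)
    mean(as.integer(drop(base %*% w) >= 0.5) == y_val)
  }
  opt_cfg <- hybrid_seek_config(
    population_size = config$fusion_population,
    max_iterations = config$fusion_iterations,
    bounds = c(0, 1), seed = derive_seed(config$seed, 103L))
  res <- hs_optimize(fitness, 3L, opt_cfg)
  project_simplex(res$best_position)
}

#' Accuracy, sensitivity and specificity of binary predictions
#'
#' Positive class is 1 (preictal). `accuracy = (T_pos + T_neg) /
#' (R_pos + R_neg)`, `sensitivity = T_pos / R_pos`, `specificity =
#' T_neg / R_neg`; a metric whose class is absent from the truth is `NA`
#' with a warning.
#'
#' @param predicted,truth Equal-length label vectors in `{0, 1}`.
#' @return List with the three metrics and the counts `T_pos`, `T_neg`,
#'   `R_pos`, `R_neg`.
#' @export
evaluate_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  t_pos <- sum(predicted == 1L & truth == 1L)
  t_neg <- sum(predicted == 0L & truth == 0L)
  r_pos <- sum(truth == 1L)
  r_neg <- sum(truth == 0L)
  sens <- if (r_pos > 0) t_pos / r_pos else {
    warning("no positive cases; sensitivity undefined"); NA_real_
  }
  spec <- if (r_neg > 0) t_neg / r_neg else {
    warning("no negative cases; specificity undefined"); NA_real_
  }
  list(accuracy = (t_pos + t_neg) / (r_pos + r_neg),
       sensitivity = sens, specificity = spec,
       T_pos = t_pos, T_neg = t_neg, R_pos = r_pos, R_neg = r_neg)
}

train_pipeline_model <- function(X_train, y_train, config, seed) {
  mask <- rep(TRUE, ncol(X_train))
  if (config$select_features && ncol(X_train) >= 2) {
    sel_cfg <- config
    sel_cfg$seed <- seed
    mask <- select_features(X_train, y_train, sel_cfg)$mask
  }
  Xm <- X_train[, mask, drop = FALSE]
  fit_idx <- stratified_split(y_train, 0.75, derive_seed(seed, 7L))
  if (length(unique(y_train[fit_idx])) < 2 ||
      length(unique(y_train[!fit_idx])) < 2) {
    fit_idx <- rep(TRUE, length(y_train))   # too small to hold out: reuse
  }
  X_fit <- Xm[fit_idx, , drop = FALSE]
  y_fit <- y_train[fit_idx]
  ab <- adaboost_train(X_fit, y_fit, rounds = config$adaboost_rounds)
  rf <- rf_train(X_fit, y_fit, R = config$rf_trees,
                 seed = derive_seed(seed, 8L))
  dt <- dt_train(X_fit, y_fit, max_depth = config$dt_max_depth)
  X_val <- Xm[!fit_idx, , drop = FALSE]
  y_val <- y_train[!fit_idx]
  if (!nrow(X_val)) { X_val <- X_fit; y_val <- y_fit }
  tune_cfg <- config
  tune_cfg$seed <- seed
  w <- tune_fusion_weights(ab, rf, dt, X_val, y_val, tune_cfg)
  list(model = ensemble_model(ab, rf, dt, w), mask = mask)
}

#' Run an evaluation protocol over a feature dataset
#'
#' Training-percentage mode trains one full pipeline (selection, base
#' models, fusion tuning) per listed percentage on a stratified split and
#' evaluates on the remainder; k-fold mode averages the metrics over
#' stratified folds for each listed k. Sub-seeds are derived
#' deterministically from the global seed per protocol point and fold.
#'
#' @param X Feature matrix.
#' @param y Labels in `{0, 1}`, both classes present.
#' @param config A [pipeline_config()] with an active protocol.
#' @return A data frame with one row per protocol point (k-fold rows are
#'   fold means): `protocol`, `value`, `accuracy`, `sensitivity`,
#'   `specificity`, `T_pos`, `T_neg`, `R_pos`, `R_neg`.
#' @export
run_protocol <- function(X, y, config) {
  if (is.null(config$protocol)) stop("no evaluation protocol configured")
  if (length(unique(y)) < 2) stop("dataset contains a single class")
  X <- as.matrix(X)
  rows <- list()
  if (config$protocol == "trainpct") {
    for (i in seq_along(config$train_percentages)) {
      pct <- config$train_percentages[i]
      seed_i <- derive_seed(config$seed, 1000L + i)
      tr <- stratified_split(y, pct / 100, seed_i)
      fit <- train_pipeline_model(X[tr, , drop = FALSE], y[tr], config, seed_i)
      pred <- fuse_predict(fit$model, X[!tr, fit$mask, drop = FALSE])
      m <- evaluate_metrics(pred$labels, y[!tr])
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "trainpct", value = pct, accuracy = m$accuracy,
        sensitivity = m$sensitivity, specificity = m$specificity,
        T_pos = m$T_pos, T_neg = m$T_neg, R_pos = m$R_pos, R_neg = m$R_neg)
    }
  } else {
    for (i in seq_along(config$k_values)) {
      k <- config$k_values[i]
      seed_i <- derive_seed(config$seed, 2000L + i)
      fold <- stratified_folds(y, k, seed_i)
      per_fold <- list()
      for (f in seq_len(k)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) {
          warning(sprintf("fold %d of k=%d misses a class; excluded", f, k))
          next
        }
        fit <- train_pipeline_model(X[tr, , drop = FALSE], y[tr], config,
                                    derive_seed(seed_i, f))
        pred <- fuse_predict(fit$model, X[!tr, fit$mask, drop = FALSE])
        m <- evaluate_metrics(pred$labels, y[!tr])
        per_fold[[length(per_fold) + 1L]] <- m
      }
      agg <- function(name) mean(vapply(per_fold, `[[`, 0, name))
      rows[[length(rows) + 1L]] <- data.frame(
        protocol = "kfold", value = k, accuracy = agg("accuracy"),
        sensitivity = agg("sensitivity"), specificity = agg("specificity"),
        T_pos = agg("T_pos"), T_neg = agg("T_neg"),
        R_pos = agg("R_pos"), R_neg = agg("R_neg"))
    }
  }
  do.call(rbind, rows)
}

format_metrics_report <- function(results, config) {
  header <- c("hybridseek metrics report v1",
              sprintf("seed %d", config$seed),
              sprintf("protocol %s", config$protocol),
              "protocol\tvalue\taccuracy\tsensitivity\tspecificity\tT_pos\tT_neg\tR_pos\tR_neg")
  body <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    sprintf("%s\t%g\t%.6f\t%.6f\t%.6f\t%.3f\t%.3f\t%.3f\t%.3f",
            r$protocol, r$value, r$accuracy, r$sensitivity, r$specificity,
            r$T_pos, r$T_neg, r$R_pos, r$R_neg)
  }, "")
  paste(c(header, body, ""), collapse = "\n")
}

#' Full record-to-report pipeline
#'
#' Preprocesses each record (optional downsampling, 0-75 Hz band-pass),
#' cuts labelled windows, decomposes them into the five bands, extracts the
#' feature vectors, and evaluates the configured protocol with wrapper
#' feature selection, the three base models and tuned fusion weights.
#' Identical config and seed produce a byte-identical metrics report.
#'
#' @param inputs A list of [eeg_record()]s, of [synth_record_config()]s
#'   (generated on the fly), or a character vector of EDF paths.
#' @param config A [pipeline_config()] with an active protocol.
#' @param out_dir Optional directory; when given, writes `features.csv`,
#'   `metrics_report.txt`, `model.rds` (the final model trained on the
#'   first protocol point) and `run_config.txt` there.
#' @return List with `features` (the extracted dataset), `results` (the
#'   protocol data frame), and `report` (the report text).
#' @export
run_end_to_end <- function(inputs, config, out_dir = NULL) {
  if (is.null(config$protocol)) stop("no evaluation protocol configured")
  if (inherits(inputs, c("eeg_record", "synth_record_config"))) {
    inputs <- list(inputs)
  }
  records <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) x <- read_edf(x)
    if (inherits(x, "synth_record_config")) x <- generate_record(x)
    if (!inherits(x, "eeg_record")) stop("unsupported input at position ", i)
    x
  })
  all_segs <- list()
  rate_out <- NULL
  for (i in seq_along(records)) {
    rec <- records[[i]]
    if (!is.null(config$downsample_hz) &&
        config$downsample_hz < rec$sampling_rate_hz) {
      rec <- downsample(rec, config$downsample_hz)
    }
    rec <- bandpass_preprocess(rec, config$bandpass_low_hz,
                               config$bandpass_high_hz)
    if (is.null(rate_out)) rate_out <- rec$sampling_rate_hz
    if (abs(rate_out - rec$sampling_rate_hz) > 1e-9) {
      stop("records have differing sampling rates after preprocessing; ",
           "set downsample_hz to a common rate")
    }
    segs <- segment_and_label(rec, config$window_s,
                              config$preictal_horizon_s, config$guard_s,
                              source_id = paste0("record", i))
    all_segs <- c(all_segs, segs)
  }
  if (!length(all_segs)) stop("segmentation produced no usable windows")
  feats <- segments_to_features(all_segs, rate_out,
                                cfg = config$wavelet, n_bins = config$n_bins)
  results <- run_protocol(feats$X, feats$y, config)
  report <- format_metrics_report(results, config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    df <- as.data.frame(feats$X)
    df$label <- feats$y
    df$source_id <- feats$meta$source_id
    df$start_s <- feats$meta$start_s
    utils::write.csv(df, file.path(out_dir, "features.csv"), row.names = FALSE)
    writeLines(report, file.path(out_dir, "metrics_report.txt"), sep = "")
    fit <- train_pipeline_model(feats$X, feats$y, config,
                                derive_seed(config$seed, 9999L))
    save_ensemble(fit$model, file.path(out_dir, "model.rds"))
    cfg_lines <- vapply(names(unclass(config)), function(nm) {
      v <- config[[nm]]
      sprintf("%s: %s", nm, paste(format(unlist(v)), collapse = ", "))
    }, "")
    writeLines(cfg_lines, file.path(out_dir, "run_config.txt"))
  }
  list(features = feats, results = results, report = report)
}
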