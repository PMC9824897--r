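# The three base classifiers and their weighted fusion. Labels are handled
# internally in {-1, +1} for AdaBoost (sign-form strong classifier) and in
# {0, 1} elsewhere; every base model exposes a class-1 score in [0, 1] so
# the convex fusion is well-defined.

## ---- decision stumps and AdaBoost ------------------------------------

stump_predict <- function(stump, X) {
  side <- ifelse(X[, stump$feature] > stump$threshold, 1, -1)
  as.numeric(side * stump$polarity)
}

fit_stump <- function(X, y_pm, weights) {
  n <- nrow(X)
  best <- list(err = Inf)
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j], method = "radix")
    xv <- X[ord, j]
    wy <- (weights * y_pm)[ord]
    # err(threshold after position i, polarity +1) for predict(+1 when x > thr):
    # misclassified weight = sum w[y==+1, x<=thr] + sum w[y==-1, x>thr]
    cum_pos <- cumsum(pmax(wy, 0))            # weight of +1 labels up to i
    tot_neg <- sum(pmax(-wy, 0))
    cum_neg <- cumsum(pmax(-wy, 0))
    distinct <- c(xv[-n] != xv[-1], TRUE)     # valid cut after position i
    err_plus <- cum_pos + (tot_neg - cum_neg) # thr after position i
    err_all_plus <- tot_neg                   # thr below min: everything is +1
    errs <- c(err_all_plus, err_plus[distinct])
    thrs <- c(xv[1] - 1, ((xv + c(xv[-1], xv[n] + 2)) / 2)[distinct])
    for (p in c(1, -1)) {
      e <- if (p == 1) errs else 1 - errs
      i_best <- which.min(e)
      if (e[i_best] < best$err - 1e-12) {
        best <- list(feature = j, threshold = thrs[i_best], polarity = p,
                     err = e[i_best])
      }
    }
  }
  best
}

#' Weighted classification error of a weak learner
#'
#' \eqn{\phi_c = \sum_s p_s \, 1[u(v_s) \ne t_s]} over normalized sample
#' weights.
#'
#' @param predictions,labels Vectors in `{-1, +1}` (or any comparable
#'   codes), equal length.
#' @param sample_weights Nonnegative weights summing to 1 (tolerance 1e-9).
#' @return The weighted error in `[0, 1]`.
#' @export
weighted_error <- function(predictions, labels, sample_weights) {
  if (any(sample_weights < 0) || abs(sum(sample_weights) - 1) > 1e-9) {
    stop("sample_weights must be nonnegative and sum to 1")
  }
  sum(sample_weights[predictions != labels])
}

#' Weak-learner weight from its weighted error
#'
#' \eqn{\tau_c = \frac12 \ln((1 - \phi_c) / \phi_c)}, with the error clamped
#' into `[1e-10, 1 - 1e-10]` first.
#'
#' @param phi Weighted error.
#' @return The learner weight.
#' @export
learner_weight <- function(phi) {
  phi <- pmin(pmax(phi, 1e-10), 1 - 1e-10)
  0.5 * log((1 - phi) / phi)
}

#' Train an AdaBoost ensemble of decision stumps
#'
#' Each round fits the stump minimizing the weighted error, computes its
#' weight via [learner_weight()], and reweights the samples multiplicatively
#' (`p <- p * exp(-tau * t * u(v))`, renormalized). Training halts early if
#' a round's stump has weighted error >= 0.5 (no informative stump left) or
#' classifies perfectly.
#'
#' @param X Numeric feature matrix.
#' @param y Labels in `{0, 1}` (mapped internally to `{-1, +1}`).
#' @param rounds Maximum number of boosting rounds, default 20.
#' @return An `adaboost_model` with the stump list and weights.
#' @export
adaboost_train <- function(X, y, rounds = 20L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  y_pm <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  weights <- rep(1 / n, n)
  stumps <- list()
  taus <- numeric(0)
  for (c_i in seq_len(rounds)) {
    st <- fit_stump(X, y_pm, weights)
    pred <- stump_predict(st, X)
    phi <- weighted_error(pred, y_pm, weights)
    if (phi >= 0.5) break
    tau <- learner_weight(phi)
    stumps[[length(stumps) + 1L]] <- st
    taus <- c(taus, tau)
    weights <- weights * exp(-tau * y_pm * pred)
    weights <- weights / sum(weights)
    if (phi <= 0) break
  }
  if (!length(stumps)) {         # first stump already uninformative
    st <- fit_stump(X, y_pm, weights)
    stumps <- list(st)
    taus <- learner_weight(weighted_error(stump_predict(st, X), y_pm, weights))
  }
  structure(list(stumps = stumps, taus = taus), class = "adaboost_model")
}

#' Predict with an AdaBoost model
#'
#' @param object An `adaboost_model`.
#' @param X Feature matrix.
#' @param type `"score"` for the class-1 score in `[0, 1]` (margin squashed
#'   by the total weight), `"label"` for `{0, 1}` labels (the sign form).
#' @param ... Unused.
#' @return Numeric vector of scores or integer labels.
#' @export
predict.adaboost_model <- function(object, X, type = c("score", "label"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  margin <- rowSums(vapply(seq_along(object$stumps), function(i) {
    object$taus[i] * stump_predict(object$stumps[[i]], X)
  }, numeric(nrow(X))))
  total <- sum(abs(object$taus))
  score <- if (total > 0) pmin(pmax((margin / total + 1) / 2, 0), 1) else rep(0.5, nrow(X))
  if (type == "score") score else as.integer(score >= 0.5)
}

## ---- Gini trees -------------------------------------------------------

#' Gini impurity of a class distribution
#'
#' \eqn{1 - \sum_\chi V_\chi^2} over class proportions.
#'
#' @param p Nonnegative class proportions summing to 1 (tolerance 1e-9).
#' @return Impurity in `[0, 1)`.
#' @export
gini_impurity <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class proportions must be nonnegative and sum to 1")
  }
  1 - sum(p^2)
}

node_gini <- function(n1, n) {
  if (n == 0) return(0)
  p <- n1 / n
  1 - p^2 - (1 - p)^2
}

best_split <- function(X, y, feature_idx) {
  n <- length(y)
  n1 <- sum(y)
  parent <- node_gini(n1, n)
  best <- NULL
  best_gain <- 1e-12
  for (j in feature_idx) {
    ord <- order(X[, j], method = "radix")
    xv <- X[ord, j]
    yv <- y[ord]
    cum1 <- cumsum(yv)
    ii <- seq_len(n - 1L)
    valid <- xv[ii] != xv[ii + 1L]
    if (!any(valid)) next
    nl <- ii[valid]
    l1 <- cum1[ii][valid]
    gl <- 1 - (l1 / nl)^2 - ((nl - l1) / nl)^2
    nr <- n - nl
    r1 <- n1 - l1
    gr <- 1 - (r1 / nr)^2 - ((nr - r1) / nr)^2
    gain <- parent - (nl * gl + nr * gr) / n
    thr <- (xv[ii][valid] + xv[ii + 1L][valid]) / 2
    # deterministic ties: lowest feature index, then lowest threshold
    k <- which(gain > best_gain + 1e-12)
    if (length(k)) {
      k <- k[which.max(gain[k])]
      kk <- which(abs(gain - gain[k]) <= 1e-12)
      k <- kk[which.min(thr[kk])]
      best_gain <- gain[k]
      best <- list(feature = j, threshold = thr[k], gain = gain[k])
    }
  }
  best
}

grow_tree <- function(X, y, depth, max_depth, min_leaf, h = NULL) {
  n <- length(y)
  n1 <- sum(y)
  leaf <- function() list(leaf = TRUE, prop1 = if (n) n1 / n else 0.5, n = n)
  if (n < 2L * min_leaf || depth >= max_depth || n1 == 0L || n1 == n) {
    return(leaf())
  }
  feats <- seq_len(ncol(X))
  if (!is.null(h) && h < length(feats)) feats <- sort(sample(feats, h))
  sp <- best_split(X, y, feats)
  if (is.null(sp)) return(leaf())
  left <- X[, sp$feature] <= sp$threshold
  if (sum(left) < min_leaf || sum(!left) < min_leaf) return(leaf())
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1L,
                        max_depth, min_leaf, h),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1L,
                         max_depth, min_leaf, h))
}

tree_score_one <- function(node, x) {
  while (!node$leaf) {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  node$prop1
}

#' Train a Gini decision tree
#'
#' Greedy recursive binary splitting on the split with the largest Gini
#' impurity decrease; ties are broken deterministically by lowest feature
#' index, then lowest threshold. Leaves store the class-1 proportion.
#'
#' @param X Feature matrix.
#' @param y Labels in `{0, 1}`.
#' @param max_depth Maximum tree depth, default 8.
#' @param min_leaf Minimum samples per leaf, default 1.
#' @return A `dt_model`.
#' @export
dt_train <- function(X, y, max_depth = 8L, min_leaf = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples")
  structure(list(root = grow_tree(X, as.integer(y), 0L, max_depth, min_leaf)),
            class = "dt_model")
}

#' Predict with a decision tree
#'
#' @param object A `dt_model`.
#' @param X Feature matrix.
#' @param type `"score"` (leaf class-1 proportion) or `"label"`.
#' @param ... Unused.
#' @return Scores in `[0, 1]` or labels in `{0, 1}`.
#' @export
predict.dt_model <- function(object, X, type = c("score", "label"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  score <- vapply(seq_len(nrow(X)), function(i) {
    tree_score_one(object$root, X[i, ])
  }, 0)
  if (type == "score") score else as.integer(score >= 0.5)
}

#' Train a random forest
#'
#' Grows `R` unpruned Gini trees, each on a bootstrap sample of size `Q = n`
#' with `h` candidate features redrawn at every node (`h < D` required).
#' Prediction is the majority vote; the score is the vote fraction.
#'
#' @param X Feature matrix.
#' @param y Labels in `{0, 1}`.
#' @param R Number of trees, default 50.
#' @param h Features sampled per node, default `floor(sqrt(D))`.
#' @param seed Integer seed; the same seed yields an identical forest.
#' @param max_depth Safety depth cap for the unpruned trees, default 30.
#' @param bootstrap Set `FALSE` to train every tree on the full sample.
#' @return An `rf_model`.
#' @export
rf_train <- function(X, y, R = 50L, h = NULL, seed = 1L, max_depth = 30L,
                     bootstrap = TRUE) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (is.null(h)) h <- max(1L, floor(sqrt(D)))
  if (h >= D && D > 1L) stop("h must be smaller than the feature count D")
  if (R < 1) stop("R must be at least 1")
  y <- as.integer(y)
  n <- nrow(X)
  trees <- with_seed(seed, {
    lapply(seq_len(R), function(r) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      grow_tree(X[idx, , drop = FALSE], y[idx], 0L, max_depth, 1L,
                h = if (D > 1L) h else NULL)
    })
  })
  structure(list(trees = trees, h = h), class = "rf_model")
}

#' Predict with a random forest
#'
#' @param object An `rf_model`.
#' @param X Feature matrix.
#' @param type `"score"` (fraction of trees voting class 1) or `"label"`.
#' @param ... Unused.
#' @return Scores in `[0, 1]` or labels in `{0, 1}`.
#' @export
predict.rf_model <- function(object, X, type = c("score", "label"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)
  votes <- vapply(object$trees, function(tr) {
    vapply(seq_len(nrow(X)), function(i) {
      as.numeric(tree_score_one(tr, X[i, ]) >= 0.5)
    }, 0)
  }, numeric(nrow(X)))
  score <- if (is.matrix(votes)) rowMeans(votes) else mean(votes)
  if (type == "score") score else as.integer(score >= 0.5)
}

## ---- weighted fusion --------------------------------------------------

#' Bundle the three base models with fusion weights
#'
#' @param adaboost,forest,tree Trained base models.
#' @param weights Length-3 fusion weights `(tau, rho, epsilon)` on the unit
#'   simplex (sum 1 within 1e-9, each in `[0, 1]`).
#' @return An `ensemble_model`.
#' @export
ensemble_model <- function(adaboost, forest, tree, weights = rep(1 / 3, 3)) {
  weights <- as.numeric(weights)
  if (length(weights) != 3 || any(weights < -1e-12) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("fusion weights must be 3 values on the unit simplex")
  }
  structure(list(adaboost = adaboost, forest = forest, tree = tree,
                 weights = pmax(weights, 0)),
            class = "ensemble_model")
}

#' Fused ensemble prediction
#'
#' `E_c = tau * E_AB + rho * E_RF + eps * E_DT` over the base models'
#' class-1 scores; the label is 1 iff `E_c >= 0.5`.
#'
#' @param model An [ensemble_model()].
#' @param X Feature matrix.
#' @return List with `scores` (fused, in `[0, 1]`), `labels` (`{0, 1}`),
#'   and `base` (matrix of the three base score vectors).
#' @export
fuse_predict <- function(model, X) {
  if (!inherits(model, "ensemble_model")) stop("not an ensemble_model")
  w <- model$weights
  if (abs(sum(w) - 1) > 1e-9) stop("fusion weights are off the simplex")
  base <- cbind(AB = predict(model$adaboost, X, type = "score"),
                RF = predict(model$forest, X, type = "score"),
                DT = predict(model$tree, X, type = "score"))
  scores <- drop(base %*% w)
  list(scores = scores, labels = as.integer(scores >= 0.5), base = base)
}

## ---- serialization ----------------------------------------------------

#' Save an ensemble model to a single archive file
#'
#' Writes a version-tagged serialized archive; [load_ensemble()] validates
#' the fusion-weight invariant on the way back in.
#'
#' @param model An [ensemble_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ensemble <- function(model, path) {
  if (!inherits(model, "ensemble_model")) stop("not an ensemble_model")
  saveRDS(list(format = "hybridseek-ensemble", version = 1L, model = model),
          path)
  invisible(path)
}

#' Load an ensemble model archive
#'
#' @param path Path written by [save_ensemble()].
#' @return The validated [ensemble_model()].
#' @export
load_ensemble <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hybridseek-ensemble")) {
    stop("not a hybridseek ensemble archive")
  }
  m <- obj$model
  if (!inherits(m, "ensemble_model") ||
      abs(sum(m$weights) - 1) > 1e-9 || any(m$weights < 0)) {
    stop("archive violates the ensemble invariants")
  }
  m
}
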