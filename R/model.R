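#' Z-score normalization statistics (training data only)
#'
#' @param train_features numeric matrix or data frame of training rows.
#' @return A `norm_stats` list with per-feature `mu`, `sigma` (sample SD)
#'   and the feature ordering.
#' @export
fit_normalizer <- function(train_features) {
  X <- as.matrix(train_features)
  if (nrow(X) < 2) stop("fit_normalizer: need at least 2 training rows")
  structure(list(mu = colMeans(X), sigma = apply(X, 2, stats::sd),
                 features = colnames(X)),
            class = "norm_stats")
}

#' Apply z-score normalization
#'
#' `x' = (x - mu) / sigma`; features with zero training variance map to 0.
#'
#' @param stats a `norm_stats` object from [fit_normalizer()].
#' @param features matrix/data frame with the same feature ordering.
#' @return Normalized numeric matrix.
#' @export
apply_normalizer <- function(stats, features) {
  X <- as.matrix(features)
  if (!is.null(colnames(X)) && !is.null(stats$features) &&
      !identical(colnames(X), stats$features)) {
    stop("apply_normalizer: feature ordering mismatch")
  }
  sig <- stats$sigma
  out <- sweep(X, 2, stats$mu, "-")
  nz <- sig > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, sig[nz], "/")
  out[, !nz] <- 0
  out
}

#' Imbalance-handling configuration
#'
#' @param smote_k number of minority nearest neighbours (default 5).
#' @param smote_ratio target minority/majority fraction after
#'   oversampling (default 0.5).
#' @param use_smote,use_weight switch the two mechanisms of the hybrid
#'   strategy independently.
#' @param use_threshold if `TRUE`, the decision threshold is moved to the
#'   Youden-optimal point on validation scores; otherwise it stays 0.5.
#' @return An `imbalance_config` list.
#' @export
imbalance_config <- function(smote_k = 5, smote_ratio = 0.5,
                             use_smote = TRUE, use_weight = TRUE,
                             use_threshold = TRUE) {
  stopifnot(smote_k >= 1, smote_ratio > 0, smote_ratio <= 1)
  structure(list(smote_k = as.integer(smote_k), smote_ratio = smote_ratio,
                 use_smote = use_smote, use_weight = use_weight,
                 use_threshold = use_threshold),
            class = "imbalance_config")
}

#' SMOTE minority oversampling
#'
#' For each synthetic point a minority sample `x_i` is taken round-robin,
#' one of its `k` nearest minority neighbours `x_hat` is drawn uniformly
#' (Euclidean distance; intended to run in normalized space), and the
#' point `x_i + delta * (x_hat - x_i)` with `delta ~ U[0,1]` is emitted.
#' The synthetic count is `round(smote_ratio * N_neg) - N_pos`, floored at
#' zero. Apply to training folds only.
#'
#' @param X numeric matrix of features (normalized).
#' @param y binary labels (1 = minority/fatigue).
#' @param cfg an [imbalance_config()].
#' @return List `X`, `y` with synthetic minority rows appended, plus
#'   `n_synthetic`.
#' @export
smote_oversample <- function(X, y, cfg = imbalance_config()) {
  X <- as.matrix(X)
  pos <- which(y == 1)
  neg <- which(y == 0)
  n_syn <- max(0L, round(cfg$smote_ratio * length(neg)) - length(pos))
  if (n_syn == 0L) return(list(X = X, y = y, n_synthetic = 0L))
  if (length(pos) < 2) {
    warning("smote_oversample: fewer than 2 minority samples; skipped")
    return(list(X = X, y = y, n_synthetic = 0L))
  }
  k <- cfg$smote_k
  if (length(pos) <= k) {
    warning("smote_oversample: k truncated to ", length(pos) - 1L)
    k <- length(pos) - 1L
  }
  P <- X[pos, , drop = FALSE]
  D <- as.matrix(stats::dist(P))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))

  base_idx <- rep_len(seq_len(nrow(P)), n_syn)
  nb_pick <- sample.int(k, n_syn, replace = TRUE)
  delta <- stats::runif(n_syn)
  Xi <- P[base_idx, , drop = FALSE]
  Xh <- P[nn[cbind(base_idx, nb_pick)], , drop = FALSE]
  Xnew <- Xi + delta * (Xh - Xi)
  list(X = rbind(X, Xnew), y = c(y, rep(1L, n_syn)), n_synthetic = n_syn)
}

#' Per-fold positive-class weight
#'
#' Ratio of negative to positive training-fold counts, computed on the
#' fold's original (pre-SMOTE) labels so that the weight reflects the real
#' imbalance rather than the rebalanced one.
#'
#' @param y_train_fold binary labels of one training fold.
#' @return `N_neg / N_pos`.
#' @export
fold_pos_weight <- function(y_train_fold) {
  n_pos <- sum(y_train_fold == 1)
  if (n_pos == 0) stop("fold_pos_weight: fold has no positive samples")
  sum(y_train_fold == 0) / n_pos
}

#' Boosting hyperparameters
#'
#' Defaults follow the study configuration: learning rate 0.01, 500
#' estimators, maximum depth 8, row subsample 0.7, column subsample 0.8.
#'
#' @param learning_rate,n_estimators,max_depth,subsample,colsample,
#'   reg_lambda,reg_alpha standard gradient-boosting controls.
#' @return A `boost_params` list.
#' @export
boost_params <- function(learning_rate = 0.01, n_estimators = 500,
                         max_depth = 8, subsample = 0.7, colsample = 0.8,
                         reg_lambda = 1, reg_alpha = 0) {
  structure(list(learning_rate = learning_rate,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth), subsample = subsample,
                 colsample = colsample, reg_lambda = reg_lambda,
                 reg_alpha = reg_alpha),
            class = "boost_params")
}

#' Weighted binary log-loss gradient and hessian
#'
#' The cost-sensitive objective scales the positive-class gradient (and
#' hessian) by `w_pos`: `g_i = (sigma(score_i) - y_i) * w_i` with
#' `w_i = w_pos` for positives and 1 for negatives. This is exactly what a
#' per-instance weight does to the log-loss, so the boosting wrapper
#' implements the weighting as instance weights; this function exists as
#' the explicit form used by the equivalence test.
#'
#' @param scores raw (logit) scores.
#' @param y binary labels.
#' @param w_pos positive-class weight.
#' @return List `grad`, `hess`.
#' @export
weighted_logloss_grad <- function(scores, y, w_pos) {
  p <- 1 / (1 + exp(-scores))
  w <- ifelse(y == 1, w_pos, 1)
  list(grad = (p - y) * w, hess = p * (1 - p) * w)
}

#' Train the cost-sensitive boosted classifier
#'
#' Gradient-boosted trees on weighted binary log-loss: positives carry
#' instance weight `w_pos`, negatives 1. Deterministic given `seed`
#' (single thread, seeded row/column subsampling).
#'
#' @param X numeric feature matrix (normalized).
#' @param y binary labels.
#' @param w_pos positive-class weight (1 = unweighted).
#' @param params a [boost_params()].
#' @param seed integer seed for the boosting RNG.
#' @return An `xgb.Booster`.
#' @export
train_cost_sensitive_gbt <- function(X, y, w_pos = 1,
                                     params = boost_params(), seed = 42) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    bad <- which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0)
    stop("train_cost_sensitive_gbt: non-finite features in rows ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  stopifnot(all(y %in% c(0, 1)))
  w <- ifelse(y == 1, w_pos, 1)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = w)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$learning_rate,
                  max_depth = params$max_depth,
                  subsample = params$subsample,
                  colsample_bytree = params$colsample,
                  lambda = params$reg_lambda, alpha = params$reg_alpha,
                  nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = params$n_estimators, verbose = 0)
}

#' Youden-optimal decision threshold
#'
#' Exhaustive search over the unique scores plus \{0, 1\} for the
#' threshold maximizing `J(Th) = sensitivity + specificity - 1` under
#' "predict positive iff score >= Th". Ties are broken toward the smallest
#' threshold, which favours sensitivity (safety-first).
#'
#' @param scores predicted probabilities in \[0, 1\].
#' @param y binary labels (both classes required).
#' @return List `threshold`, `j` (the maximal Youden J).
#' @export
optimal_threshold <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  if (length(unique(y)) < 2) {
    stop("optimal_threshold: both classes must be present")
  }
  cand <- sort(unique(c(0, scores, 1)))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & y == 1) / n_pos + sum(!pred & y == 0) / n_neg - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)[1] # smallest threshold wins ties
  list(threshold = cand[best], j = max(j))
}

#' Train the full fatigue model on a training partition
#'
#' The deployable unit: fits the normalizer on the training rows, runs an
#' inner stratified 5-fold CV purely to collect pooled out-of-fold
#' validation scores (per-fold pre-SMOTE positive weight, per-fold SMOTE),
#' moves the decision threshold to the Youden optimum of those pooled
#' scores, then refits on the full training partition. Test rows must
#' never enter this function.
#'
#' @param X training feature matrix (raw scale).
#' @param y binary labels.
#' @param imbalance an [imbalance_config()].
#' @param params a [boost_params()].
#' @param seed integer seed (controls folds, SMOTE draws, boosting RNG).
#' @param inner_folds inner CV folds for threshold selection (default 5).
#' @return A `fatigue_model`: norm stats, booster, w_pos, threshold,
#'   feature names, config and seed.
#' @export
train_fatigue_model <- function(X, y, imbalance = imbalance_config(),
                                params = boost_params(), seed = 42,
                                inner_folds = 5) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  ns <- fit_normalizer(X)
  Xn <- apply_normalizer(ns, X)

  threshold <- 0.5
  if (imbalance$use_threshold && length(unique(y)) == 2 && sum(y) >= 2) {
    set.seed(seed)
    folds <- caret::createFolds(factor(y), k = inner_folds)
    oof <- rep(NA_real_, length(y))
    for (fi in seq_along(folds)) {
      idx_val <- folds[[fi]]
      Xtr <- Xn[-idx_val, , drop = FALSE]
      ytr <- y[-idx_val]
      if (sum(ytr) == 0) next
      fit <- fit_fold(Xtr, ytr, imbalance, params, seed + fi)
      oof[idx_val] <- predict(fit, Xn[idx_val, , drop = FALSE])
    }
    ok <- !is.na(oof)
    if (length(unique(y[ok])) == 2) {
      threshold <- optimal_threshold(oof[ok], y[ok])$threshold
    }
  }

  booster <- fit_fold(Xn, y, imbalance, params, seed)
  w_pos <- if (imbalance$use_weight) fold_pos_weight(y) else 1
  structure(list(norm = ns, booster = booster, w_pos = w_pos,
                 threshold = threshold, features = colnames(X),
                 imbalance = imbalance, params = params, seed = seed,
                 calibrated = FALSE),
            class = "fatigue_model")
}

# One cost-sensitive fit on (already normalized) rows: pre-SMOTE weight,
# optional SMOTE, boosted trees.
fit_fold <- function(Xn, y, imbalance, params, seed) {
  w_pos <- if (imbalance$use_weight) fold_pos_weight(y) else 1
  if (imbalance$use_smote) {
    set.seed(seed)
    sm <- smote_oversample(Xn, y, imbalance)
    Xn <- sm$X
    y <- sm$y
  }
  train_cost_sensitive_gbt(Xn, y, w_pos, params, seed)
}

#' Predict fatigue probabilities and labels
#'
#' @param object a `fatigue_model`.
#' @param newdata feature matrix/data frame on the raw scale with the
#'   model's feature ordering.
#' @param ... unused.
#' @return Data frame with `prob` and `label` (1 iff prob >= threshold).
#' @export
predict.fatigue_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!identical(colnames(X), object$features)) {
    stop("predict.fatigue_model: feature ordering mismatch")
  }
  Xn <- apply_normalizer(object$norm, X)
  prob <- predict(object$booster, xgboost::xgb.DMatrix(Xn))
  data.frame(prob = prob, label = as.integer(prob >= object$threshold))
}

#' Per-subject calibration of a trained model
#'
#' Adapts a population model to one subject using a small calibration set
#' (chronologically the subject's first windows, never reused as test):
#' the generic ensemble is frozen and (a) a small number of strongly
#' shrunk boosted trees are appended, fitted to the calibration residuals,
#' and (b) the decision threshold is re-optimized on the calibration
#' scores. Either step is skipped when the calibration labels are
#' single-class; with no calibration data the model is returned unchanged.
#'
#' @param model a `fatigue_model`.
#' @param X_cal,y_cal calibration windows (raw scale) and labels.
#' @param n_trees appended trees (default 25).
#' @param eta_cal shrinkage for the appended trees (default 0.05).
#' @param seed integer seed.
#' @return The calibrated `fatigue_model` (with `calibrated = TRUE` and a
#'   `calibration_status` field).
#' @export
calibrate_subject <- function(model, X_cal, y_cal, n_trees = 25,
                              eta_cal = 0.05, seed = 42) {
  if (is.null(X_cal) || nrow(as.matrix(X_cal)) == 0) {
    model$calibration_status <- "empty_calibration_set"
    return(model)
  }
  X <- as.matrix(X_cal)[, model$features, drop = FALSE]
  Xn <- apply_normalizer(model$norm, X)
  y <- as.integer(y_cal)
  single_class <- length(unique(y)) < 2

  status <- character(0)
  if (!single_class) {
    w_pos <- max(fold_pos_weight(y), 1)
    w <- ifelse(y == 1, w_pos, 1)
    dcal <- xgboost::xgb.DMatrix(Xn, label = y, weight = w)
    model$booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = eta_cal,
                    max_depth = model$params$max_depth,
                    nthread = 1, seed = as.integer(seed)),
      data = dcal, nrounds = n_trees, xgb_model = model$booster,
      verbose = 0)
    status <- c(status, "trees_appended")
    scores <- predict(model$booster, xgboost::xgb.DMatrix(Xn))
    model$threshold <- optimal_threshold(scores, y)$threshold
    status <- c(status, "threshold_refit")
  } else {
    status <- "skipped_single_class"
  }
  model$calibrated <- TRUE
  model$calibration_status <- paste(status, collapse = "+")
  model
}

#' Save / load a trained fatigue model
#'
#' The artifact bundles the normalization statistics, the serialized
#' ensemble, the positive weight, the moved threshold, feature ordering,
#' seed and configuration, plus a schema version and config hash.
#'
#' @param model a `fatigue_model`.
#' @param path file path (.rds).
#' @return `load_fatigue_model` returns the restored `fatigue_model`.
#' @export
save_fatigue_model <- function(model, path) {
  obj <- model
  obj$booster <- xgboost::xgb.save.raw(model$booster)
  obj$schema_version <- 1L
  obj$config_hash <- config_hash(list(model$imbalance, model$params,
                                      model$features, model$seed))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_fatigue_model
#' @export
load_fatigue_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("load_fatigue_model: unknown or missing schema version")
  }
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  obj
}

# FNV-1a hash over the serialized object; stable fingerprint for
# config provenance checks without external digest dependencies.
config_hash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
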