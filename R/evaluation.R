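#' Confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity (recall), specificity and F1 from the
#' binary confusion matrix. Ratios with zero denominators are reported as
#' 0 and flagged rather than raising, so degenerate folds never abort a
#' sweep.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return List: TP, TN, FP, FN, accuracy, precision, sensitivity,
#'   specificity, f1, flags.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) == 0) stop("confusion_metrics: empty input")
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  flags <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, paste0(what, "_undefined"))
      return(0)
    }
    num / den
  }
  acc <- (tp + tn) / length(y_true)
  prec <- safe(tp, tp + fp, "precision")
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  f1 <- safe(2 * tp, 2 * tp + fp + fn, "f1")
  list(TP = tp, TN = tn, FP = fp, FN = fn, accuracy = acc,
       precision = prec, sensitivity = sens, specificity = spec, f1 = f1,
       flags = flags)
}

#' Area under the ROC curve
#'
#' Tie-corrected concordance probability (rank formulation), identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param y_true binary labels (both classes required).
#' @param scores continuous scores.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

eval_report <- function(y_true, y_pred, scores = NULL) {
  cm <- confusion_metrics(y_true, y_pred)
  cm$auc <- if (!is.null(scores) && length(unique(y_true)) == 2) {
    roc_auc(y_true, scores)
  } else {
    NA_real_
  }
  cm
}

metric_summary <- function(reports, metrics = c("accuracy", "precision",
                                                "sensitivity", "specificity",
                                                "f1", "auc")) {
  tab <- sapply(metrics, function(m) {
    vals <- vapply(reports, function(r) r[[m]] %||% NA_real_, numeric(1))
    c(mean = mean(vals, na.rm = TRUE), sd = stats::sd(vals, na.rm = TRUE))
  })
  t(tab)
}

labeled_windows <- function(windows) {
  lw <- windows[!is.na(windows$label), , drop = FALSE]
  lw[, c("subject_id", "scenario_id", "window_index", "sp7", "label",
         FEATURE_NAMES)]
}

#' Mixed-subject evaluation (Protocol A)
#'
#' Stratified 80:20 train/test split (default seed 42); the model's inner
#' 5-fold CV on the training portion drives threshold selection; the final
#' refit is evaluated once on the untouched test portion.
#'
#' @param windows a `window_features` table.
#' @param imbalance an [imbalance_config()].
#' @param params a [boost_params()].
#' @param seed split seed (default 42).
#' @param features feature subset (default the 12 fused features).
#' @return List: `report` (test-set metrics + AUC), `model`, `split`
#'   (row indices), `seed`.
#' @export
run_protocol_a <- function(windows, imbalance = imbalance_config(),
                           params = boost_params(), seed = 42,
                           features = FEATURE_NAMES) {
  lw <- labeled_windows(windows)
  y <- lw$label
  set.seed(seed)
  idx_train <- caret::createDataPartition(factor(y), p = 0.8, list = FALSE)[, 1]
  if (length(unique(y[-idx_train])) < 2) {
    stop("run_protocol_a: test split is single-class; use another seed")
  }
  X <- as.matrix(lw[, features])
  model <- train_fatigue_model(X[idx_train, , drop = FALSE], y[idx_train],
                               imbalance, params, seed)
  pr <- predict(model, X[-idx_train, , drop = FALSE])
  rep <- eval_report(y[-idx_train], pr$label, pr$prob)
  list(report = rep, model = model,
       split = list(train = idx_train, test = setdiff(seq_along(y),
                                                      idx_train)),
       seed = seed)
}

#' Leave-one-subject-out evaluation (Protocol B)
#'
#' One fold per subject: the model (normalizer, SMOTE, weight, threshold)
#' is fitted entirely on the remaining subjects and evaluated on the
#' held-out subject. Train/test subject sets are asserted disjoint every
#' fold. Held-out subjects with single-class windows get threshold metrics
#' but no AUC.
#'
#' @inheritParams run_protocol_a
#' @return List: `per_subject` (data frame of per-subject metrics),
#'   `summary` (mean/SD per metric), `pooled` (metrics over all pooled
#'   predictions), `seed`.
#' @export
run_protocol_loso <- function(windows, imbalance = imbalance_config(),
                              params = boost_params(), seed = 42,
                              features = FEATURE_NAMES) {
  lw <- labeled_windows(windows)
  subjects <- unique(lw$subject_id)
  if (length(subjects) < 3) stop("run_protocol_loso: need >= 3 subjects")
  if (length(unique(lw$label)) < 2) {
    stop("run_protocol_loso: pool must contain both classes")
  }
  X <- as.matrix(lw[, features])
  y <- lw$label
  reports <- list()
  pooled_pred <- pooled_true <- pooled_prob <- list()
  for (s in subjects) {
    test <- lw$subject_id == s
    stopifnot(length(intersect(unique(lw$subject_id[!test]),
                               unique(lw$subject_id[test]))) == 0)
    if (sum(y[!test] == 1) < 1) next
    model <- train_fatigue_model(X[!test, , drop = FALSE], y[!test],
                                 imbalance, params, seed)
    pr <- predict(model, X[test, , drop = FALSE])
    rep <- eval_report(y[test], pr$label, pr$prob)
    rep$subject_id <- s
    rep$n <- sum(test)
    reports[[s]] <- rep
    pooled_pred[[s]] <- pr$label
    pooled_prob[[s]] <- pr$prob
    pooled_true[[s]] <- y[test]
  }
  per_subject <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = r$subject_id, n = r$n, accuracy = r$accuracy,
               precision = r$precision, sensitivity = r$sensitivity,
               specificity = r$specificity, f1 = r$f1, auc = r$auc)
  }))
  rownames(per_subject) <- NULL
  pooled <- eval_report(unlist(pooled_true), unlist(pooled_pred),
                        unlist(pooled_prob))
  list(per_subject = per_subject, summary = metric_summary(reports),
       pooled = pooled, seed = seed)
}

#' Personalized-calibration experiment
#'
#' Within the LOSO framework: for each held-out subject with more than
#' `n_cal` windows, the generic model is evaluated on the windows after
#' the chronologically first `n_cal`, then calibrated on those first
#' `n_cal` windows and re-evaluated on the same post-calibration windows.
#' A paired t-test compares per-subject accuracies.
#'
#' @inheritParams run_protocol_a
#' @param n_cal calibration windows per subject (default 30).
#' @return List: `per_subject` (generic vs calibrated accuracy per
#'   subject), `mean_generic`, `mean_calibrated`, `paired_t`, `paired_p`,
#'   `excluded` (subjects with too few windows), `seed`.
#' @export
run_calibration_experiment <- function(windows,
                                       imbalance = imbalance_config(),
                                       params = boost_params(), seed = 42,
                                       n_cal = 30,
                                       features = FEATURE_NAMES) {
  lw <- labeled_windows(windows)
  X <- as.matrix(lw[, features])
  y <- lw$label
  subjects <- unique(lw$subject_id)
  rows <- list()
  excluded <- character(0)
  for (s in subjects) {
    test <- which(lw$subject_id == s)
    ord <- test[order(lw$scenario_id[test], lw$window_index[test])]
    if (length(ord) <= n_cal) {
      excluded <- c(excluded, s)
      next
    }
    if (sum(y[-test] == 1) < 1) next
    cal <- ord[seq_len(n_cal)]
    hold <- ord[-seq_len(n_cal)]
    model <- train_fatigue_model(X[-test, , drop = FALSE], y[-test],
                                 imbalance, params, seed)
    pr_gen <- predict(model, X[hold, , drop = FALSE])
    acc_gen <- mean(pr_gen$label == y[hold])
    cal_model <- calibrate_subject(model, X[cal, , drop = FALSE], y[cal],
                                   seed = seed)
    pr_cal <- predict(cal_model, X[hold, , drop = FALSE])
    acc_cal <- mean(pr_cal$label == y[hold])
    rows[[s]] <- data.frame(subject_id = s, n_test = length(hold),
                            acc_generic = acc_gen, acc_calibrated = acc_cal,
                            status = cal_model$calibration_status)
  }
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  tt <- if (!is.null(per_subject) && nrow(per_subject) >= 2 &&
            stats::sd(per_subject$acc_calibrated -
                      per_subject$acc_generic) > 0) {
    stats::t.test(per_subject$acc_calibrated, per_subject$acc_generic,
                  paired = TRUE)
  } else {
    NULL
  }
  list(per_subject = per_subject,
       mean_generic = mean(per_subject$acc_generic),
       mean_calibrated = mean(per_subject$acc_calibrated),
       paired_t = if (is.null(tt)) 0 else unname(tt$statistic),
       paired_p = if (is.null(tt)) 1 else tt$p.value,
       excluded = excluded, seed = seed)
}

#' Ablation harness: modality subsets x imbalance strategies
#'
#' Runs the classifier under stratified 5-fold CV for every combination of
#' modality subset (eye-only 8-D, ECG-only 4-D, 12-D fusion) and imbalance
#' strategy (none, weight-only, smote-only, hybrid). "None" means unit
#' weight, no SMOTE and a fixed 0.5 threshold; only the hybrid strategy
#' moves the threshold.
#'
#' @inheritParams run_protocol_a
#' @param modalities subset of c("eye", "ecg", "fusion").
#' @param strategies subset of c("none", "weight", "smote", "hybrid").
#' @param n_folds outer CV folds (default 5).
#' @return Data frame: one row per modality x strategy with mean and SD of
#'   accuracy, AUC, sensitivity and F1 across folds.
#' @export
ablation_harness <- function(windows, params = boost_params(), seed = 42,
                             modalities = c("eye", "ecg", "fusion"),
                             strategies = c("none", "weight", "smote",
                                            "hybrid"),
                             n_folds = 5) {
  strat_cfg <- list(
    none = imbalance_config(use_smote = FALSE, use_weight = FALSE,
                            use_threshold = FALSE),
    weight = imbalance_config(use_smote = FALSE, use_weight = TRUE,
                              use_threshold = FALSE),
    smote = imbalance_config(use_smote = TRUE, use_weight = FALSE,
                             use_threshold = FALSE),
    hybrid = imbalance_config(use_smote = TRUE, use_weight = TRUE,
                              use_threshold = TRUE)
  )
  bad <- setdiff(strategies, names(strat_cfg))
  if (length(bad)) stop("ablation_harness: unknown strategy ", bad[1])
  feat_sets <- list(eye = OCULAR_FEATURES, ecg = CARDIAC_FEATURES,
                    fusion = FEATURE_NAMES)
  lw <- labeled_windows(windows)
  y <- lw$label
  set.seed(seed)
  folds <- caret::createFolds(factor(y), k = n_folds)
  out <- list()
  for (mod in modalities) {
    X <- as.matrix(lw[, feat_sets[[mod]]])
    for (strat in strategies) {
      cfg <- strat_cfg[[strat]]
      reports <- list()
      for (fi in seq_along(folds)) {
        idx_test <- folds[[fi]]
        model <- train_fatigue_model(X[-idx_test, , drop = FALSE],
                                     y[-idx_test], cfg, params, seed + fi)
        pr <- predict(model, X[idx_test, , drop = FALSE])
        reports[[fi]] <- eval_report(y[idx_test], pr$label, pr$prob)
      }
      ms <- metric_summary(reports)
      out[[paste(mod, strat)]] <- data.frame(
        modality = mod, strategy = strat, n_features = ncol(X),
        accuracy = ms["accuracy", "mean"], accuracy_sd = ms["accuracy", "sd"],
        auc = ms["auc", "mean"], auc_sd = ms["auc", "sd"],
        sensitivity = ms["sensitivity", "mean"],
        sensitivity_sd = ms["sensitivity", "sd"],
        f1 = ms["f1", "mean"], f1_sd = ms["f1", "sd"])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Friedman test with Nemenyi post hoc
#'
#' Classic Friedman chi-square from average within-block ranks (larger
#' metric = better = higher rank), followed by pairwise Nemenyi
#' critical-difference comparisons at the given alpha. Blocks are CV folds
#' or subjects; columns are models.
#'
#' @param metric_matrix numeric matrix, blocks in rows, models in columns.
#' @param alpha significance level for the critical difference.
#' @return List: chi2, df, p, mean_ranks, cd (critical difference),
#'   pairwise (data frame of model pairs with rank differences and
#'   significance). Constant input yields chi2 = 0, p = 1 and no post hoc.
#' @export
friedman_nemenyi <- function(metric_matrix, alpha = 0.05) {
  M <- as.matrix(metric_matrix)
  b <- nrow(M)
  k <- ncol(M)
  if (k < 2 || b < 2) stop("friedman_nemenyi: need >= 2 models and blocks")
  if (is.null(colnames(M))) colnames(M) <- paste0("model", seq_len(k))
  ranks <- t(apply(M, 1, rank)) # average ranks on ties
  rbar <- colMeans(ranks)
  chi2 <- 12 * b / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  p <- stats::pchisq(chi2, df = k - 1, lower.tail = FALSE)
  if (chi2 == 0) {
    return(list(chi2 = 0, df = k - 1, p = 1, mean_ranks = rbar,
                cd = NA_real_, pairwise = NULL))
  }
  q_alpha <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q_alpha * sqrt(k * (k + 1) / (6 * b))
  pairs <- utils::combn(k, 2)
  pairwise <- data.frame(
    model_a = colnames(M)[pairs[1, ]],
    model_b = colnames(M)[pairs[2, ]],
    rank_diff = abs(rbar[pairs[1, ]] - rbar[pairs[2, ]])
  )
  pairwise$significant <- pairwise$rank_diff > cd
  list(chi2 = chi2, df = k - 1, p = p, mean_ranks = rbar, cd = cd,
       pairwise = pairwise)
}
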