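test_that("z-score normalization matches hand arithmetic and guards", {
  X <- cbind(a = c(0, 2), b = c(5, 5))
  ns <- fit_normalizer(X)
  Z <- apply_normalizer(ns, X)
  expect_equal(Z[, "a"], c(-1, 1) / sqrt(2), ignore_attr = TRUE)
  expect_equal(Z[, "b"], c(0, 0), ignore_attr = TRUE)  # constant column
  # a row at the training mean maps to the zero vector
  expect_equal(as.numeric(apply_normalizer(ns, cbind(a = 1, b = 5))),
               c(0, 0))
  expect_error(apply_normalizer(ns, cbind(b = 1, a = 5)), "ordering")
  expect_error(fit_normalizer(X[1, , drop = FALSE]), "2 training rows")
})

test_that("SMOTE emits convex combinations with the contracted count", {
  d <- make_feature_data(n_neg = 170, n_pos = 10, seed = 2)
  set.seed(7)
  sm <- smote_oversample(d$X, d$y, imbalance_config(smote_ratio = 1.0))
  # round(1.0 * 170) - 10 = 160 synthetic positives
  expect_equal(sm$n_synthetic, 160)
  expect_equal(sum(sm$y == 1), 170)
  P <- d$X[d$y == 1, ]
  syn <- sm$X[-seq_len(nrow(d$X)), , drop = FALSE]
  # each synthetic point lies on a segment between two real minority points
  for (i in seq_len(nrow(syn))) {
    res <- Inf
    for (a in seq_len(nrow(P))) {
      for (b in seq_len(nrow(P))) {
        if (a == b) next
        dir <- P[b, ] - P[a, ]
        tt <- sum((syn[i, ] - P[a, ]) * dir) / sum(dir^2)
        if (tt < -1e-9 || tt > 1 + 1e-9) next
        res <- min(res, sqrt(sum((syn[i, ] - P[a, ] - tt * dir)^2)))
      }
    }
    expect_lt(res, 1e-9)
  }
})

test_that("SMOTE degenerate cases are guarded", {
  d <- make_feature_data(n_neg = 20, n_pos = 3, seed = 3)
  set.seed(1)
  expect_warning(sm <- smote_oversample(d$X, d$y, imbalance_config()),
                 "truncated")
  expect_gt(sm$n_synthetic, 0)

  d1 <- make_feature_data(n_neg = 20, n_pos = 1, seed = 4)
  expect_warning(sm1 <- smote_oversample(d1$X, d1$y, imbalance_config()),
                 "skipped")
  expect_equal(sm1$n_synthetic, 0)

  # already balanced -> nothing to add
  db <- make_feature_data(n_neg = 10, n_pos = 10, seed = 5)
  sm2 <- smote_oversample(db$X, db$y, imbalance_config(smote_ratio = 0.5))
  expect_equal(sm2$n_synthetic, 0)
})

test_that("fold positive weight is the plain negative:positive ratio", {
  expect_equal(fold_pos_weight(c(rep(0, 2655), rep(1, 157))), 2655 / 157,
               tolerance = 1e-12)
  expect_equal(round(fold_pos_weight(c(rep(0, 2655), rep(1, 157))), 2),
               16.91)
  expect_equal(fold_pos_weight(c(0, 1, 0, 1)), 1)
  expect_equal(fold_pos_weight(c(rep(0, 90), rep(1, 30))), 3)
  expect_error(fold_pos_weight(rep(0, 5)), "no positive")
})

test_that("cost-sensitive weighting equals the scaled-gradient form", {
  # hand case: y = 1, sigma(score) = 0.3 -> gradient (0.3 - 1) * w_pos
  s <- log(0.3 / 0.7)
  g <- weighted_logloss_grad(s, 1, w_pos = 5)
  expect_equal(g$grad, (0.3 - 1) * 5, tolerance = 1e-12)
  expect_equal(g$hess, 0.3 * 0.7 * 5, tolerance = 1e-12)
  # negatives keep unit weight
  g0 <- weighted_logloss_grad(s, 0, w_pos = 5)
  expect_equal(g0$grad, 0.3, tolerance = 1e-12)

  # w_pos = 1 reproduces unweighted training exactly
  d <- make_feature_data(seed = 6)
  m1 <- train_cost_sensitive_gbt(d$X, d$y, w_pos = 1, seed = 9)
  m2 <- train_cost_sensitive_gbt(d$X, d$y, w_pos = 1, seed = 9)
  p1 <- predict(m1, xgboost::xgb.DMatrix(d$X))
  p2 <- predict(m2, xgboost::xgb.DMatrix(d$X))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the booster separates linearly separable data", {
  set.seed(10)
  X <- rbind(matrix(stats::rnorm(100, 0), 50, 2),
             matrix(stats::rnorm(100, 4), 50, 2))
  colnames(X) <- c("u", "v")
  y <- rep(0:1, each = 50)
  m <- train_cost_sensitive_gbt(X, y, w_pos = 1, seed = 1)
  p <- predict(m, xgboost::xgb.DMatrix(X))
  expect_gt(roc_auc(y, p), 0.99)
})

test_that("Youden threshold search matches the spec example and a grid", {
  res <- optimal_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$j, 0.5)
  expect_equal(res$threshold, 0.35)

  # perfectly separated -> J = 1; all-identical scores -> J = 0
  expect_equal(optimal_threshold(c(0.1, 0.2, 0.8, 0.9),
                                 c(0, 0, 1, 1))$j, 1)
  expect_equal(optimal_threshold(rep(0.5, 6), c(0, 0, 0, 1, 1, 1))$j, 0)

  expect_error(optimal_threshold(c(0.2, 0.4), c(1, 1)), "both classes")

  # brute-force grid oracle on 100 random instances
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
    s <- round(stats::runif(n), 3)
    res <- optimal_threshold(s, y)
    grid <- seq(0, 1, by = 1e-4)
    j_grid <- vapply(grid, function(th) {
      pred <- s >= th
      sum(pred & y == 1) / sum(y == 1) +
        sum(!pred & y == 0) / sum(y == 0) - 1
    }, numeric(1))
    expect_equal(res$j, max(j_grid), tolerance = 1e-9)
  }
})

test_that("trained models predict deterministically and round-trip", {
  d <- make_feature_data(n_neg = 120, n_pos = 18, seed = 12)
  m <- train_fatigue_model(d$X, d$y, seed = 42,
                           params = boost_params(n_estimators = 120))
  m2 <- train_fatigue_model(d$X, d$y, seed = 42,
                            params = boost_params(n_estimators = 120))
  pr <- predict(m, d$X)
  expect_equal(pr$prob, predict(m2, d$X)$prob, tolerance = 1e-12)
  expect_true(m$threshold >= 0 && m$threshold <= 1)
  expect_equal(m$w_pos, 120 / 18)

  path <- tempfile(fileext = ".rds")
  save_fatigue_model(m, path)
  m3 <- load_fatigue_model(path)
  expect_equal(predict(m3, d$X)$prob, pr$prob, tolerance = 1e-12)
  expect_identical(m3$threshold, m$threshold)
  unlink(path)

  # threshold semantics
  m$threshold <- 0
  expect_true(all(predict(m, d$X)$label == 1))
  m$threshold <- 1 + 1e-9
  expect_true(all(predict(m, d$X)$label == 0))

  # name-based selection makes column order irrelevant ...
  expect_equal(predict(m, d$X[, c(2, 1, 3, 4)])$prob, pr$prob)
  # ... but a missing feature is a hard error
  expect_error(predict(m, d$X[, 1:3]), "subscript|ordering|undefined")
})

test_that("subject calibration is guarded and refits the threshold", {
  d <- make_feature_data(n_neg = 150, n_pos = 20, seed = 13)
  m <- train_fatigue_model(d$X, d$y, seed = 42,
                           params = boost_params(n_estimators = 80))

  # empty calibration set: identical model back
  m0 <- calibrate_subject(m, d$X[0, ], integer(0))
  expect_equal(m0$threshold, m$threshold)
  expect_equal(m0$calibration_status, "empty_calibration_set")

  # single-class calibration set: no-op with status
  mc1 <- calibrate_subject(m, d$X[1:10, ], rep(0L, 10))
  expect_equal(mc1$threshold, m$threshold)
  expect_match(mc1$calibration_status, "single_class")
  expect_equal(predict(mc1, d$X)$prob, predict(m, d$X)$prob)

  # mixed calibration set: trees appended, threshold refit
  idx <- c(1:15, 151:155)
  mc2 <- calibrate_subject(m, d$X[idx, ], d$y[idx], seed = 1)
  expect_match(mc2$calibration_status, "trees_appended")
  expect_match(mc2$calibration_status, "threshold_refit")
})

test_that("calibration helps a subject with a shifted baseline", {
  # population model trained on unshifted subjects; the target subject's
  # features carry an additive baseline offset (as a shifted resting
  # heart rate would produce); calibration sees the subject's first
  # windows with both classes present
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    pop <- make_feature_data(n_neg = 160, n_pos = 24, p = 4, sep = 2.5,
                             seed = s)
    m <- train_fatigue_model(pop$X, pop$y, seed = s,
                             params = boost_params(n_estimators = 80))
    shift <- c(1.5, -1.5, 0.8, 0)
    subj <- make_feature_data(n_neg = 40, n_pos = 10, p = 4, sep = 2.5,
                              seed = 1000 + s)
    Xs <- sweep(subj$X, 2, shift, "+")
    ord <- sample(50)
    cal <- ord[1:25]
    hold <- ord[26:50]
    if (length(unique(subj$y[cal])) < 2) return(NA)
    acc_gen <- mean(predict(m, Xs[hold, ])$label == subj$y[hold])
    mc <- calibrate_subject(m, Xs[cal, ], subj$y[cal], seed = s)
    acc_cal <- mean(predict(mc, Xs[hold, ])$label == subj$y[hold])
    acc_cal >= acc_gen
  }, logical(1))
  expect_gt(mean(wins, na.rm = TRUE), 0.5)
})

test_that("leakage guard: fitters only ever see training rows", {
  d <- make_feature_data(n_neg = 100, n_pos = 15, seed = 14)
  test_idx <- sample(115, 20)
  Xtr <- d$X[-test_idx, ]
  ytr <- d$y[-test_idx]
  m <- train_fatigue_model(Xtr, ytr, seed = 7,
                           params = boost_params(n_estimators = 50))
  # normalization statistics derive from training rows only
  expect_equal(m$norm$mu, colMeans(Xtr))
  expect_equal(m$norm$sigma, apply(Xtr, 2, stats::sd))
  # w_pos from training labels only
  expect_equal(m$w_pos, sum(ytr == 0) / sum(ytr == 1))
})
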