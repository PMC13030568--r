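#' Canonical feature orderings
#'
#' `FEATURE_NAMES` is the fixed 12-dimensional fused ordering (8 ocular
#' features followed by 4 cardiac features); `OCULAR_FEATURES` and
#' `CARDIAC_FEATURES` are the modality subsets used by the ablations.
#'
#' @export
FEATURE_NAMES <- c("PERCLOS", "BF", "MBD", "MFD", "FF", "PDV", "SGE", "TGE",
                   "MeanRR", "SDNN", "RMSSD", "LFHF")

#' @rdname FEATURE_NAMES
#' @export
OCULAR_FEATURES <- FEATURE_NAMES[1:8]

#' @rdname FEATURE_NAMES
#' @export
CARDIAC_FEATURES <- FEATURE_NAMES[9:12]

#' Segment scenarios into 60-second windows
#'
#' Non-overlapping half-open windows `[start + 60k, start + 60(k+1))`
#' aligned to the scenario start; trailing partial windows are dropped.
#' Scenarios shorter than the window length produce zero windows.
#'
#' @param sessions session table (`subject_id`, `scenario_id`,
#'   `start_s`, `end_s`, `sp7_post`).
#' @param window_s window length, s (default 60).
#' @return Data frame of window shells: subject_id, scenario_id,
#'   window_index (1-based), t0, t1, sp7.
#' @export
segment_windows <- function(sessions, window_s = 60) {
  out <- lapply(seq_len(nrow(sessions)), function(i) {
    row <- sessions[i, ]
    n_win <- floor((row$end_s - row$start_s) / window_s)
    if (n_win < 1) return(NULL)
    k <- seq_len(n_win)
    data.frame(subject_id = row$subject_id, scenario_id = row$scenario_id,
               window_index = k,
               t0 = row$start_s + (k - 1) * window_s,
               t1 = row$start_s + k * window_s,
               sp7 = row$sp7_post)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), scenario_id = character(0),
                      window_index = integer(0), t0 = numeric(0),
                      t1 = numeric(0), sp7 = integer(0))
  }
  out
}

#' Assign extreme-group fatigue labels from SP-7 scores
#'
#' SP-7 1-3 map to alert (0), 5-7 to fatigue (1); the transitional score 4
#' is excluded (`NA` label, retained in the table but never used for model
#' fitting).
#'
#' @param windows window table with an `sp7` column.
#' @return The table with a `label` column (0 / 1 / NA).
#' @export
assign_labels <- function(windows) {
  sp7 <- windows$sp7
  if (any(!sp7 %in% 1:7)) {
    stop("assign_labels: sp7 scores must be integers in 1..7")
  }
  windows$label <- ifelse(sp7 <= 3, 0L, ifelse(sp7 >= 5, 1L, NA_integer_))
  windows
}

#' Fuse ocular and cardiac features into one vector
#'
#' Serial (early-fusion) concatenation in the fixed order PERCLOS, BF,
#' MBD, MFD, FF, PDV, SGE, TGE, MeanRR, SDNN, RMSSD, LFHF (D = 12). No
#' scaling happens here; normalization is a training-set-only model stage.
#'
#' @param ocular named list/vector with the 8 ocular features.
#' @param cardiac named list/vector with the 4 cardiac features.
#' @param modality "fusion" (12-D), "eye" (8-D) or "ecg" (4-D ablations).
#' @return Named numeric vector.
#' @export
fuse_features <- function(ocular, cardiac, modality = "fusion") {
  take <- function(src, nms) {
    v <- unlist(src[nms])
    if (length(v) != length(nms) || any(is.na(v))) {
      stop("fuse_features: missing feature component(s): ",
           paste(setdiff(nms, names(src)), collapse = ", "))
    }
    v
  }
  switch(modality,
    fusion = c(take(ocular, OCULAR_FEATURES), take(cardiac, CARDIAC_FEATURES)),
    eye = take(ocular, OCULAR_FEATURES),
    ecg = take(cardiac, CARDIAC_FEATURES),
    stop("fuse_features: unknown modality '", modality, "'")
  )
}

#' Extract the windowed feature table from a cohort
#'
#' Runs the full signal pipeline per scenario (wavelet denoising +
#' Pan-Tompkins on the ECG; blink repair + I-VT on the gaze stream), then
#' computes the 12 fused features per 60-s window and applies the quality
#' rules: a window is rejected when more than `max_invalid` of its gaze
#' samples are invalid, when its cardiac features are unusable, or when
#' its heart rate is implausible. Rejections are logged in the `dropped`
#' attribute with reasons.
#'
#' @param cohort a [gen_cohort()] result (with signals), or a list with
#'   `sessions`, `gaze`, `ecg`, `grid` read from disk.
#' @param window_s window length, s.
#' @param velocity_threshold I-VT threshold, deg/s.
#' @param max_invalid maximum tolerated invalid-gaze fraction per window.
#' @return A `window_features` data frame: metadata (subject_id,
#'   scenario_id, window_index, sp7, label), the 12 feature columns and a
#'   `flags` column; attribute `dropped` lists rejected windows.
#' @export
extract_features <- function(cohort, window_s = 60, velocity_threshold = 30,
                             max_invalid = 0.30) {
  stopifnot(!is.null(cohort$gaze), !is.null(cohort$ecg))
  grid <- cohort$grid %||% aoi_grid()
  shells <- assign_labels(segment_windows(cohort$sessions, window_s))
  rows <- vector("list", nrow(shells))
  dropped <- list()

  for (sc in unique(shells$scenario_id)) {
    sel <- which(shells$scenario_id == sc)
    sess <- cohort$sessions[cohort$sessions$scenario_id == sc, ]
    gaze <- cohort$gaze[[sc]]
    ecg <- cohort$ecg[[sc]]
    if (is.null(gaze) || is.null(ecg)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(scenario_id = sc, window_index = NA, reason = "no_signal")
      next
    }
    po <- parse_ocular(gaze, velocity_threshold = velocity_threshold)
    peaks <- pan_tompkins(wavelet_denoise(ecg))
    # streams are recorded relative to scenario start
    for (i in sel) {
      sh <- shells[i, ]
      w <- c(sh$t0 - sess$start_s, sh$t1 - sess$start_s)
      in_w <- po$stream$t >= w[1] & po$stream$t < w[2]
      inval <- mean(!po$stream$valid[in_w])
      if (isTRUE(attr(po$stream, "unusable")) || inval > max_invalid) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          scenario_id = sc, window_index = sh$window_index,
          reason = "gaze_invalid")
        next
      }
      oc <- ocular_features(po$stream, po$events, w, grid)
      cf <- cardiac_features(peaks, w)
      if (!isTRUE(cf$usable)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          scenario_id = sc, window_index = sh$window_index,
          reason = "cardiac_unusable")
        next
      }
      feats <- fuse_features(oc, cf)
      rows[[i]] <- cbind(
        sh[, c("subject_id", "scenario_id", "window_index", "sp7", "label")],
        as.data.frame(as.list(feats)),
        flags = paste(unique(c(oc$flags, cf$flags)), collapse = ";")
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(scenario_id = character(0), window_index = integer(0),
               reason = character(0))
  class(out) <- c("window_features", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate SP-7 labels against PERCLOS
#'
#' Two checks on the cleaned (post-exclusion) window table: Spearman rank
#' correlation between per-window SP-7 score and PERCLOS, and an
#' independent two-sample t-test of PERCLOS between the alert and fatigue
#' groups (pooled variance by default).
#'
#' @param windows a `window_features` table (needs `sp7`, `label`,
#'   `PERCLOS`).
#' @param var_equal pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return List: spearman_r, spearman_p, t_stat, t_p, status ("ok" or
#'   "t_test_skipped" when a group is empty).
#' @export
validate_labels <- function(windows, var_equal = TRUE) {
  lab <- windows[!is.na(windows$label), , drop = FALSE]
  ct <- suppressWarnings(
    stats::cor.test(lab$sp7, lab$PERCLOS, method = "spearman"))
  res <- list(spearman_r = unname(ct$estimate), spearman_p = ct$p.value,
              t_stat = NA_real_, t_p = NA_real_, status = "ok")
  g0 <- lab$PERCLOS[lab$label == 0]
  g1 <- lab$PERCLOS[lab$label == 1]
  if (length(g0) < 2 || length(g1) < 2) {
    res$status <- "t_test_skipped"
    return(res)
  }
  tt <- stats::t.test(g0, g1, var.equal = var_equal)
  res$t_stat <- unname(tt$statistic)
  res$t_p <- tt$p.value
  res
}
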