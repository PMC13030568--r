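IO_SCHEMA_VERSION <- 1L

# Write a CSV with a provenance comment header (schema + config hash);
# readers skip comment lines.
write_artifact_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fatiguefusion schema=%d config=%s",
                     IO_SCHEMA_VERSION,
                     if (is.null(config)) "none" else config_hash(config)),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, ": file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, ": ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

check_rate <- function(t, nominal, what, path, tol = 0.01) {
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop(what, ": ", path, ": time must be strictly increasing (line ",
         which(dt <= 0)[1] + 1L, ")")
  }
  fs <- 1 / stats::median(dt)
  if (abs(fs - nominal) / nominal > tol) {
    stop(what, ": ", path, ": sampling rate ", round(fs, 2),
         " Hz outside ", nominal, " Hz +/- ", tol * 100, "%")
  }
  fs
}

#' Read a gaze stream CSV
#'
#' Expected columns: `t_s`, `x_deg`, `y_deg`, `pupil_mm` and optionally
#' `valid`. The sampling rate is inferred from the time column and
#' validated against the nominal rate (+/- 1%).
#'
#' @param path CSV path (comment lines starting with `#` are skipped).
#' @param nominal_fs nominal sampling rate, Hz.
#' @return A `gaze_stream`.
#' @export
read_gaze <- function(path, nominal_fs = 100) {
  df <- read_csv_checked(path, c("t_s", "x_deg", "y_deg", "pupil_mm"),
                         "read_gaze")
  check_rate(df$t_s, nominal_fs, "read_gaze", path)
  if (any(df$pupil_mm < 0)) stop("read_gaze: ", path, ": negative pupil")
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else
    df$pupil_mm > 0
  gaze_stream(t = df$t_s, x = df$x_deg, y = df$y_deg, pupil = df$pupil_mm,
              valid = valid, fs = nominal_fs)
}

#' Read an ECG trace CSV
#'
#' Expected columns: `t_s`, `mv`.
#'
#' @inheritParams read_gaze
#' @param nominal_fs nominal sampling rate, Hz (default 512).
#' @return An `ecg_trace`.
#' @export
read_ecg <- function(path, nominal_fs = 512) {
  df <- read_csv_checked(path, c("t_s", "mv"), "read_ecg")
  check_rate(df$t_s, nominal_fs, "read_ecg", path)
  if (any(!is.finite(df$mv))) stop("read_ecg: ", path, ": non-finite values")
  ecg_trace(t = df$t_s, v = df$mv, fs = nominal_fs)
}

#' Read a session table CSV
#'
#' Expected columns: `subject_id`, `scenario_id`, `scenario_type`,
#' `start_s`, `end_s`, `sp7_post` (1-7).
#'
#' @inheritParams read_gaze
#' @return Session data frame (column names normalized to `start_s`,
#'   `end_s` internally used as `start_s`/`end_s`).
#' @export
read_sessions <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "scenario_id",
                                 "scenario_type", "start_s", "end_s",
                                 "sp7_post"), "read_sessions")
  if (any(df$end_s <= df$start_s)) {
    stop("read_sessions: ", path, ": end_s must exceed start_s (line ",
         which(df$end_s <= df$start_s)[1] + 1L, ")")
  }
  if (any(!df$sp7_post %in% 1:7)) {
    stop("read_sessions: ", path, ": sp7_post out of range 1-7 (line ",
         which(!df$sp7_post %in% 1:7)[1] + 1L, ")")
  }
  for (s in unique(df$subject_id)) {
    sub <- df[df$subject_id == s, ]
    sub <- sub[order(sub$start_s), ]
    if (nrow(sub) > 1 && any(sub$start_s[-1] < sub$end_s[-nrow(sub)])) {
      stop("read_sessions: ", path, ": overlapping scenarios for subject ",
           s)
    }
  }
  df
}

#' Write a cohort to disk as CSV artifacts
#'
#' Emits `sessions.csv` plus per-scenario `gaze_<id>.csv` and
#' `ecg_<id>.csv` in the same dialects [read_gaze()], [read_ecg()] and
#' [read_sessions()] consume (times relative to scenario start).
#'
#' @param cohort a [gen_cohort()] result with signals.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_artifact_csv(cohort$sessions, file.path(dir, "sessions.csv"),
                     cohort$config)
  for (sc in names(cohort$gaze)) {
    g <- cohort$gaze[[sc]]
    write_artifact_csv(
      data.frame(t_s = g$t, x_deg = g$x, y_deg = g$y, pupil_mm = g$pupil,
                 valid = g$valid),
      file.path(dir, paste0("gaze_", sc, ".csv")), cohort$config)
    e <- cohort$ecg[[sc]]
    write_artifact_csv(data.frame(t_s = e$t, mv = e$v),
                       file.path(dir, paste0("ecg_", sc, ".csv")),
                       cohort$config)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `sessions.csv` and per-scenario
#'   gaze/ECG CSVs.
#' @param grid an [aoi_grid()] for downstream feature extraction.
#' @return A list compatible with [extract_features()].
#' @export
read_cohort <- function(dir, grid = aoi_grid()) {
  sessions <- read_sessions(file.path(dir, "sessions.csv"))
  gaze <- list()
  ecg <- list()
  for (sc in sessions$scenario_id) {
    gaze[[sc]] <- read_gaze(file.path(dir, paste0("gaze_", sc, ".csv")))
    ecg[[sc]] <- read_ecg(file.path(dir, paste0("ecg_", sc, ".csv")))
  }
  list(sessions = sessions, gaze = gaze, ecg = ecg, grid = grid)
}

#' Pipeline run configuration
#'
#' Bundles every tunable constant of the pipeline with its standard
#' default: 30 deg/s I-VT velocity threshold, 75-500 ms blink bounds,
#' 150 ms integration window, sym8/8-level denoising, SMOTE k = 5,
#' 60-s windows and seed 42.
#'
#' @param path optional YAML file; keys override the defaults below.
#' @return A `run_config` list.
#' @export
run_config <- function(path = NULL) {
  cfg <- list(
    window_s = 60,
    velocity_threshold = 30,
    blink_bounds = c(75, 500),
    min_fix_dur = 100,
    mwi_ms = 150,
    wavelet_levels = 8,
    aoi_rows = 4, aoi_cols = 8,
    max_invalid = 0.30,
    smote_k = 5, smote_ratio = 0.5,
    learning_rate = 0.01, n_estimators = 500, max_depth = 8,
    subsample = 0.7, colsample = 0.8,
    n_cal = 30,
    seed = 42
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  structure(cfg, class = "run_config")
}

#' Write / read the window feature table
#'
#' One row per window: metadata columns (subject_id, scenario_id,
#' window_index, sp7, label) plus the 12 named feature columns and flags.
#'
#' @param windows a `window_features` table.
#' @param path CSV path.
#' @return `read_feature_table` returns the `window_features` table.
#' @export
write_feature_table <- function(windows, path) {
  write_artifact_csv(windows, path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read_csv_checked(path, c("subject_id", "scenario_id",
                                 "window_index", "sp7", FEATURE_NAMES),
                         "read_feature_table")
  if (!"label" %in% names(df)) df <- assign_labels(df)
  df$label <- as.integer(df$label)
  class(df) <- c("window_features", "data.frame")
  df
}
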