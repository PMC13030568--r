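#' Cohort generation configuration
#'
#' Describes a multi-subject, multi-scenario recording campaign. The
#' default rates reproduce the window-level class mix observed in
#' screen-based control-room studies: roughly 77% alert (SP-7 1-3), 18.5%
#' transitional (SP-7 4, later excluded) and 4.55% fatigue (SP-7 5-7),
#' i.e. a ~17:1 alert:fatigue imbalance after exclusion.
#'
#' @param n_subjects number of subjects (default 36).
#' @param scenarios_per_subject scenarios per subject (default 10).
#' @param scenario_len_s scenario length, s (>= 60; default 600).
#' @param subject_baseline_sd SD of the log-normal multiplicative
#'   per-subject offset applied to mean RR, pupil base and fixation
#'   duration (default 0.30; resting heart rate and fixation style vary
#'   strongly between individuals, which is what limits cross-subject
#'   transfer).
#' @param subject_ocular_sd SD of the log-normal per-subject offset on
#'   blink duration and closure rate (default 0.20; spontaneous blink
#'   behaviour varies widely between individuals).
#' @param state_jitter_sd SD of the scenario-level Gaussian jitter between
#'   the subjective SP-7 rating and the physiological state position on
#'   the alert-fatigue continuum (default 0.20 on the \[0, 1\] scale);
#'   models the imperfect coupling of self-report and physiology.
#' @param fatigue_prevalence fraction of scenarios rated fatigued
#'   (default 0.0455).
#' @param transition_prevalence fraction of scenarios rated SP-7 = 4
#'   (default 0.185).
#' @param seed integer master seed (default 42).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 36, scenarios_per_subject = 10,
                          scenario_len_s = 600, subject_baseline_sd = 0.30,
                          subject_ocular_sd = 0.25, state_jitter_sd = 0.20,
                          fatigue_prevalence = 0.0455,
                          transition_prevalence = 0.185, seed = 42) {
  if (scenario_len_s < 60) stop("cohort_config: scenario_len_s must be >= 60")
  if (fatigue_prevalence <= 0 || fatigue_prevalence >= 1) {
    stop("cohort_config: fatigue_prevalence must be in (0, 1)")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    scenarios_per_subject = as.integer(scenarios_per_subject),
    scenario_len_s = scenario_len_s,
    subject_baseline_sd = subject_baseline_sd,
    subject_ocular_sd = subject_ocular_sd,
    state_jitter_sd = state_jitter_sd,
    fatigue_prevalence = fatigue_prevalence,
    transition_prevalence = transition_prevalence,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# SP-7 score frequencies within each state category (used to draw a
# concrete post-scenario rating once the category is fixed).
SP7_ALERT_WEIGHTS <- c(`1` = 1245, `2` = 890, `3` = 520)
SP7_FATIGUE_WEIGHTS <- c(`5` = 112, `6` = 35, `7` = 10)

#' Generate a synthetic multimodal cohort
#'
#' Draws per-subject baseline offsets once, assigns each scenario a
#' vigilance state (alert / transition / fatigue, exact proportional
#' counts shuffled uniformly over all subject-scenarios) and a
#' post-scenario SP-7 rating, then (optionally) synthesizes the gaze and
#' ECG streams for every scenario with regime parameters interpolated
#' between the alert and fatigue presets according to the SP-7 score.
#'
#' @param config a [cohort_config()].
#' @param grid an [aoi_grid()] used for gaze generation.
#' @param signals if `FALSE`, only the session table and window-level
#'   ground truth are produced (fast; signal lists are `NULL`).
#' @return A `cohort` list: `sessions` (subject_id, scenario_id,
#'   scenario_type, start_s, end_s, sp7_post), `gaze`/`ecg` (named lists of
#'   streams per scenario_id), `truth` (per-window ground-truth table plus
#'   per-scenario generator truths), `config`, `grid`.
#' @export
gen_cohort <- function(config = cohort_config(), grid = aoi_grid(),
                       signals = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  ns <- config$n_subjects
  nsc <- config$scenarios_per_subject
  n_total <- ns * nsc
  len <- config$scenario_len_s

  subjects <- sprintf("S%02d", seq_len(ns))
  baselines <- lapply(seq_len(ns), function(i) {
    c(mean_rr = stats::rlnorm(1, 0, config$subject_baseline_sd),
      pupil_base = stats::rlnorm(1, 0, config$subject_baseline_sd),
      fix_dur_mean = stats::rlnorm(1, 0, config$subject_baseline_sd),
      blink_dur_mean = stats::rlnorm(1, 0, config$subject_ocular_sd),
      closure_rate = stats::rlnorm(1, 0, config$subject_ocular_sd))
  })
  names(baselines) <- subjects

  n_fat <- max(1L, round(config$fatigue_prevalence * n_total))
  n_trn <- round(config$transition_prevalence * n_total)
  states <- sample(c(rep("fatigue", n_fat), rep("transition", n_trn),
                     rep("alert", n_total - n_fat - n_trn)))

  sp7 <- integer(n_total)
  is_f <- states == "fatigue"
  is_t <- states == "transition"
  sp7[is_f] <- as.integer(sample(names(SP7_FATIGUE_WEIGHTS), sum(is_f),
                                 replace = TRUE, prob = SP7_FATIGUE_WEIGHTS))
  sp7[is_t] <- 4L
  sp7[!is_f & !is_t] <- as.integer(
    sample(names(SP7_ALERT_WEIGHTS), sum(!is_f & !is_t),
           replace = TRUE, prob = SP7_ALERT_WEIGHTS))

  gap <- 300 # rest break between scenarios, s
  sessions <- data.frame(
    subject_id = rep(subjects, each = nsc),
    scenario_id = sprintf("%s_R%02d", rep(subjects, each = nsc),
                          rep(seq_len(nsc), ns)),
    scenario_type = rep_len(c(1L, 2L, 1L, 2L, 3L), n_total),
    start_s = rep((seq_len(nsc) - 1L) * (len + gap), ns),
    end_s = rep((seq_len(nsc) - 1L) * (len + gap) + len, ns),
    sp7_post = sp7,
    state = states
  )

  alert <- alert_regime()
  fatigue <- fatigue_regime()
  n_win <- floor(len / 60)
  gaze_list <- ecg_list <- scen_truth <- list()
  win_rows <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    row <- sessions[i, ]
    w <- (row$sp7_post - 1) / 6
    # subjective rating tracks the physiological state only loosely
    w <- min(max(w + stats::rnorm(1, 0, config$state_jitter_sd), 0), 1)
    params <- regime_interpolate(alert, fatigue, w)
    # eyelid-closure behaviour responds early and saturates: blink
    # duration and closure rate follow sqrt(w), steep across the alert
    # range and flattening toward deep fatigue
    p_ocu <- regime_interpolate(alert, fatigue, sqrt(w))
    params$closure_rate <- p_ocu$closure_rate
    params$blink_dur_mean <- p_ocu$blink_dur_mean
    params <- regime_apply_baseline(params, baselines[[row$subject_id]])

    rr_t <- ecg_t <- gz_t <- NULL
    if (signals) {
      rrg <- gen_rr_series(params, len)
      eg <- gen_ecg(rrg, duration = len)
      gg <- gen_gaze_stream(params, grid, len)
      gaze_list[[row$scenario_id]] <- gg$gaze
      ecg_list[[row$scenario_id]] <- eg$ecg
      rr_t <- rrg$truth
      ecg_t <- eg$truth
      gz_t <- gg$truth
      scen_truth[[row$scenario_id]] <- list(rr = rr_t, ecg = ecg_t,
                                            gaze = gz_t)
    }

    win_rows[[i]] <- data.frame(
      subject_id = row$subject_id,
      scenario_id = row$scenario_id,
      window_index = seq_len(n_win),
      sp7 = row$sp7_post,
      state = row$state,
      true_mean_rr = params$mean_rr,
      true_rmssd = params$rmssd_target,
      true_lfhf_tone = (params$lf_amp^2) / (params$hf_amp^2),
      true_mbd = params$blink_dur_mean,
      true_perclos = (params$blink_rate * params$blink_dur_mean +
                        params$closure_rate * 900) / 60000,
      true_fix_dur = params$fix_dur_mean
    )
  }

  windows <- do.call(rbind, win_rows)
  lbl <- ifelse(windows$sp7 <= 3, 0L, ifelse(windows$sp7 >= 5, 1L, NA))
  if (sum(lbl == 1L, na.rm = TRUE) == 0) {
    warning("gen_cohort: prevalence settings produced zero fatigue windows")
  }

  structure(list(
    sessions = sessions[, setdiff(names(sessions), "state")],
    gaze = if (signals) gaze_list else NULL,
    ecg = if (signals) ecg_list else NULL,
    truth = list(windows = windows,
                 scenarios = if (signals) scen_truth else NULL,
                 baselines = baselines),
    config = config,
    grid = grid
  ), class = "cohort")
}
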