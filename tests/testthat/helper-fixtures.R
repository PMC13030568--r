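# Shared fixtures, built in code.

# A minimal uniform gaze stream with a scripted zero-pupil run.
make_gaze_with_gap <- function(gap_ms, fs = 100, dur_s = 4, gap_at_s = 2) {
  n <- dur_s * fs
  t <- (seq_len(n) - 1) / fs
  x <- rep(1, n)
  y <- rep(2, n)
  pupil <- rep(3, n)
  i0 <- gap_at_s * fs + 1
  i1 <- i0 + round(gap_ms / 1000 * fs) - 1
  pupil[i0:i1] <- 0
  gaze_stream(t = t, x = x, y = y, pupil = pupil, fs = fs)
}

# A two-segment stream: fixation at (0,0), fast jump, fixation at (5,0).
make_two_fixation_stream <- function(fs = 100, seg_s = 0.5) {
  n <- seg_s * fs
  t <- (seq_len(2 * n + 2) - 1) / fs
  x <- c(rep(0, n), 2.5, 2.5, rep(5, n))
  y <- rep(0, 2 * n + 2)
  gaze_stream(t = t, x = x, y = y, pupil = rep(3, length(t)), fs = fs)
}

# Feature matrix with a controllable class-separating direction; used by
# model-level tests that do not need the signal pipeline.
make_feature_data <- function(n_neg = 170, n_pos = 10, p = 4, sep = 3,
                              seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_neg * p), n_neg, p),
             matrix(stats::rnorm(n_pos * p, mean = sep / sqrt(p)), n_pos, p))
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = c(rep(0L, n_neg), rep(1L, n_pos)))
}

# Small cached cohort feature table shared across expensive tests.
cohort_features_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(seed, n_subjects = 8, scenarios_per_subject = 12,
           scenario_len_s = 240) {
    key <- paste0("s", seed, "_", n_subjects, "_", scenarios_per_subject,
                  "_", scenario_len_s)
    if (!is.null(cache[[key]])) return(cache[[key]])
    coh <- gen_cohort(cohort_config(
      n_subjects = n_subjects, scenarios_per_subject = scenarios_per_subject,
      scenario_len_s = scenario_len_s, seed = seed))
    wf <- extract_features(coh)
    cache[[key]] <- wf
    wf
  }
})
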