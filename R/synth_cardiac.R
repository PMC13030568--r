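#' Generate a synthetic RR tachogram
#'
#' Emits an RR-interval series with controllable spectral structure: each
#' interval is `mean_rr + lf_amp * sin(2*pi*0.10*t) + hf_amp *
#' sin(2*pi*0.25*t) + N(0, rmssd_target/sqrt(2))`, with `t` the cumulative
#' beat time. The 0.10 / 0.25 Hz tones sit at the centres of the LF
#' (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands, so the generator places
#' known power in each band and the LF/HF of the emitted series is
#' controlled by the amplitude ratio.
#'
#' @param params a [regime_params()] object.
#' @param duration recording length, s (>= 60).
#' @param seed optional integer; `NULL` uses the current RNG state.
#' @return A list with `rr` (an `rr_series` data frame: `t` interval start
#'   time in s, `rri` interval in ms, `gap` logical) and `truth`: true
#'   R-peak times (s), the generating parameters, and the empirical
#'   SDNN / RMSSD / mean RR of the emitted clean series.
#' @export
gen_rr_series <- function(params, duration, seed = NULL) {
  stopifnot(inherits(params, "regime_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("gen_rr_series: duration must be positive")
  }
  if (params$mean_rr <= 0) stop("gen_rr_series: mean_rr must be positive")
  if (duration < 60) stop("gen_rr_series: duration must be >= 60 s")
  if (!is.null(seed)) set.seed(seed)

  noise_sd <- params$rmssd_target / sqrt(2)
  # upper bound on beat count, then trim to the requested duration
  n_max <- ceiling(duration * 1000 / max(params$mean_rr - 4 * noise_sd -
    params$lf_amp - params$hf_amp, 300)) + 8L
  t <- 0
  rri <- numeric(0)
  tt <- numeric(0)
  for (i in seq_len(n_max)) {
    r <- params$mean_rr +
      params$lf_amp * sin(2 * pi * 0.10 * t) +
      params$hf_amp * sin(2 * pi * 0.25 * t) +
      stats::rnorm(1, 0, noise_sd)
    r <- max(r, 300) # physiological floor
    rri <- c(rri, r)
    tt <- c(tt, t)
    t <- t + r / 1000
    if (t >= duration) break
  }
  rr <- rr_series(t = tt, rri = rri)
  truth <- list(
    r_times = c(tt, t),
    params = params,
    mean_rr = mean(rri),
    sdnn = stats::sd(rri),
    rmssd = sqrt(mean(diff(rri)^2))
  )
  list(rr = rr, truth = truth)
}

#' RR-interval series container
#'
#' `gap[i] = TRUE` means interval i is not contiguous with interval i-1
#' (series start, or a removed ectopic beat in between), which breaks
#' successive-difference chains in RMSSD.
#'
#' @param t interval start times, s.
#' @param rri intervals, ms (positive).
#' @param gap logical gap flags (default: only the first interval).
#' @return An `rr_series` data frame.
#' @export
rr_series <- function(t, rri, gap = NULL) {
  stopifnot(length(t) == length(rri), all(rri > 0))
  if (is.null(gap)) gap <- c(TRUE, rep(FALSE, max(length(t) - 1L, 0L)))
  structure(data.frame(t = t, rri = rri, gap = gap),
            class = c("rr_series", "data.frame"))
}

# PQRST wave description: amplitude (mV), centre offset from R (ms), and
# Gaussian width (ms). A plain morphological sketch, not a lead model.
PQRST_WAVES <- list(
  P = c(amp = 0.12, mu = -180, sd = 32),
  Q = c(amp = -0.12, mu = -22, sd = 9),
  R = c(amp = 1.00, mu = 0, sd = 10),
  S = c(amp = -0.18, mu = 22, sd = 9),
  T = c(amp = 0.35, mu = 170, sd = 55)
)

#' Synthesize an ECG trace from an RR series
#'
#' Places a Gaussian-kernel PQRST template at each cumulative beat time and
#' adds baseline wander (0.2 Hz sinusoid), powerline interference (50 Hz
#' sinusoid) and white noise. R-peak times are snapped to the sample grid
#' and recorded as ground truth.
#'
#' @param rr output of [gen_rr_series()] (the list, or an `rr_series`).
#' @param fs sampling rate, Hz (default 512; must be >= 100).
#' @param noise list with `baseline_amp`, `powerline_amp`, `white_sd` (mV).
#' @param duration trace length, s; defaults to the RR series span.
#' @param seed optional integer seed.
#' @return List with `ecg` (an `ecg_trace` data frame: `t` s, `v` mV, with
#'   attribute `fs`) and `truth` (`r_times` s on the sample grid, `r_idx`
#'   0-based sample indices).
#' @export
gen_ecg <- function(rr, fs = 512,
                    noise = list(baseline_amp = 0.15, powerline_amp = 0.03,
                                 white_sd = 0.02),
                    duration = NULL, seed = NULL) {
  if (is.list(rr) && !is.null(rr$rr)) rr <- rr$rr
  stopifnot(inherits(rr, "rr_series"))
  if (fs < 100) stop("gen_ecg: fs < 100 Hz cannot resolve the QRS template")
  if (!is.null(seed)) set.seed(seed)

  # offset beats from the trace edges so every template fits completely
  edge <- 0.35
  beat_times <- edge + c(rr$t, rr$t[nrow(rr)] + rr$rri[nrow(rr)] / 1000)
  if (is.null(duration)) duration <- max(beat_times) + edge
  n <- floor(duration * fs)
  tvec <- (seq_len(n) - 1L) / fs
  v <- numeric(n)

  r_idx <- round(beat_times * fs) # 0-based grid positions
  r_idx <- r_idx[r_idx >= edge * fs - 1 & r_idx < n - edge * fs]
  for (w in PQRST_WAVES) {
    mu_s <- w[["mu"]] / 1000
    sd_s <- w[["sd"]] / 1000
    hw <- ceiling(4 * sd_s * fs)
    off <- (-hw):hw
    kern <- w[["amp"]] * exp(-0.5 * ((off / fs - mu_s) / sd_s)^2)
    centre <- round(mu_s * fs)
    for (ri in r_idx) {
      pos <- ri + centre + off + 1L
      keep <- pos >= 1L & pos <= n
      v[pos[keep]] <- v[pos[keep]] + kern[keep]
    }
  }

  phase_b <- stats::runif(1, 0, 2 * pi)
  phase_p <- stats::runif(1, 0, 2 * pi)
  v <- v +
    noise$baseline_amp * sin(2 * pi * 0.2 * tvec + phase_b) +
    noise$powerline_amp * sin(2 * pi * 50 * tvec + phase_p) +
    stats::rnorm(n, 0, noise$white_sd)

  ecg <- ecg_trace(t = tvec, v = v, fs = fs)
  list(ecg = ecg, truth = list(r_times = r_idx / fs, r_idx = r_idx))
}

#' ECG trace container
#'
#' @param t sample times, s (uniform).
#' @param v amplitudes, mV (finite).
#' @param fs sampling rate, Hz (stored as an attribute).
#' @return An `ecg_trace` data frame.
#' @export
ecg_trace <- function(t, v, fs) {
  stopifnot(length(t) == length(v), all(is.finite(v)))
  structure(data.frame(t = t, v = v),
            fs = fs, class = c("ecg_trace", "data.frame"))
}

ecg_fs <- function(trace) attr(trace, "fs")
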