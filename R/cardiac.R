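#' Wavelet ECG denoising
#'
#' 8-level sym8 decomposition with periodic boundary handling. All detail
#' coefficients are soft-thresholded with the universal threshold
#' `lambda = sigma * sqrt(2 * log(N))`, `sigma` estimated from the finest
#' detail level by MAD/0.6745; the level-8 approximation is zeroed, which
#' removes baseline drift (everything below ~1 Hz at 512 Hz sampling).
#' Traces whose length is not a multiple of `2^levels` are padded by
#' symmetric reflection and unpadded on return.
#'
#' @param trace an `ecg_trace` data frame (`t`, `v`, attr `fs`).
#' @param levels decomposition depth (default 8).
#' @return The denoised `ecg_trace`.
#' @export
wavelet_denoise <- function(trace, levels = 8) {
  v <- trace$v
  n <- length(v)
  block <- 2^levels
  if (n < 2) stop("wavelet_denoise: trace too short")
  n_pad <- block * ceiling(n / block)
  if (n_pad > n) {
    ext <- n_pad - n
    refl <- rev(v)
    while (length(refl) < ext) refl <- c(refl, refl)
    v <- c(v, refl[seq_len(ext)])
  }

  dec <- dwt_forward(v, levels)
  d1 <- dec$details[[1]]
  sigma <- stats::median(abs(d1)) / 0.6745
  lambda <- sigma * sqrt(2 * log(length(v)))
  dec$details <- lapply(dec$details, soft_threshold, lambda = lambda)
  dec$approx[] <- 0
  out <- dwt_inverse(dec)[seq_len(n)]
  ecg_trace(t = trace$t, v = out, fs = ecg_fs(trace))
}

# Soft thresholding: shrink coefficients above lambda toward zero, kill
# the rest.
soft_threshold <- function(d, lambda) {
  sign(d) * pmax(abs(d) - lambda, 0)
}

#' Pan-Tompkins R-peak detection
#'
#' Classic QRS detector: 5-15 Hz band-pass (zero-phase Butterworth),
#' five-point derivative, squaring, and moving-window integration with a
#' 150 ms window, followed by adaptive dual-threshold peak picking with a
#' 200 ms refractory period and half-threshold search-back. Detected
#' envelope peaks are refined to the local maximum of the band-passed
#' trace within +/- 40 ms.
#'
#' @param trace a (denoised) `ecg_trace`, at least 5 s long.
#' @param mwi_ms moving-window integration width, ms (default 150).
#' @param refractory_ms minimum peak spacing, ms (default 200).
#' @param hr_bounds plausible heart-rate range (bpm) used to flag the
#'   trace; outside it `attr(, "usable")` is `FALSE`.
#' @return An `r_peak_series` data frame (`t` s, `idx` 0-based sample
#'   index) with attributes `usable` and `fs`. Empty (and flagged) when no
#'   peak is found.
#' @export
pan_tompkins <- function(trace, mwi_ms = 150, refractory_ms = 200,
                         hr_bounds = c(40, 180)) {
  fs <- ecg_fs(trace)
  v <- trace$v
  n <- length(v)
  if (n < 5 * fs) stop("pan_tompkins: need at least 5 s of signal")

  if (all(v == 0)) {
    return(r_peak_series(numeric(0), integer(0), fs, usable = FALSE))
  }

  bp <- tryCatch({
    bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(bf, v))
  }, error = function(e) stop("pan_tompkins: band-pass failed: ",
                              conditionMessage(e)))

  # zero-phase 5-point derivative, then squaring
  der <- numeric(n)
  i <- 3:(n - 2)
  der[i] <- (2 * bp[i + 1] + bp[i + 2] - 2 * bp[i - 1] - bp[i - 2]) / 8
  sq <- der^2

  W <- max(3L, round(mwi_ms / 1000 * fs))
  env <- as.numeric(stats::filter(sq, rep(1 / W, W), sides = 2))
  env[is.na(env)] <- 0

  refr <- round(refractory_ms / 1000 * fs)
  peaks <- detect_adaptive_peaks(env, fs, refr)
  if (length(peaks) == 0) {
    return(r_peak_series(numeric(0), integer(0), fs, usable = FALSE))
  }

  # refine to the band-passed local maximum within +/- 40 ms
  hw <- round(0.04 * fs)
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, p - hw)
    hi <- min(n, p + hw)
    as.integer(lo + which.max(bp[lo:hi]) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  refined <- refined[keep]

  dur_s <- n / fs
  bpm <- length(refined) / dur_s * 60
  # plausibility: heart rate in range AND a physiologically regular RR
  # train (noise-driven detections have RR CV several times higher than
  # any resting rhythm)
  rr_cv <- if (length(refined) > 2) {
    rr <- diff(refined)
    stats::sd(rr) / mean(rr)
  } else {
    Inf
  }
  usable <- bpm >= hr_bounds[1] && bpm <= hr_bounds[2] && rr_cv <= 0.20
  r_peak_series(trace$t[refined], refined - 1L, fs, usable = usable)
}

# Adaptive dual-threshold scan over the integrated envelope. Returns
# 1-based sample indices of accepted envelope peaks.
detect_adaptive_peaks <- function(env, fs, refr) {
  n <- length(env)
  cand <- which(diff(sign(diff(env))) < 0) + 1L # local maxima
  cand <- cand[env[cand] > 0]
  if (!length(cand)) return(integer(0))
  # keep only maxima dominant over a half-refractory neighbourhood
  # (suppresses numerical ripple on the envelope flanks)
  w <- max(1L, round(refr / 2))
  dominant <- vapply(cand, function(p) {
    env[p] >= max(env[max(1L, p - w):min(n, p + w)])
  }, logical(1))
  cand <- cand[dominant]
  if (!length(cand)) return(integer(0))

  init <- env[seq_len(min(2 * fs, n))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)

  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (p in cand) {
    if (p - last < refr) next
    if (env[p] > thr()) {
      # search-back first: did we miss a beat in a long gap?
      if (length(rr_hist) >= 2 && is.finite(last)) {
        exp_rr <- mean(utils::tail(rr_hist, 8))
        if (p - last > 1.66 * exp_rr) {
          gapc <- cand[cand > last + refr & cand < p - refr / 2]
          gapc <- gapc[env[gapc] > 0.5 * thr()]
          if (length(gapc)) {
            sb <- gapc[which.max(env[gapc])]
            rr_hist <- c(rr_hist, sb - last)
            accepted <- c(accepted, sb)
            spki <- 0.25 * env[sb] + 0.75 * spki
            last <- sb
          }
        }
      }
      if (is.finite(last)) rr_hist <- c(rr_hist, p - last)
      accepted <- c(accepted, p)
      spki <- 0.125 * env[p] + 0.875 * spki
      last <- p
    } else {
      npki <- 0.125 * env[p] + 0.875 * npki
    }
  }
  accepted
}

#' R-peak series container
#'
#' @param t peak times, s (strictly increasing).
#' @param idx 0-based sample indices.
#' @param fs sampling rate of the source trace, Hz.
#' @param usable plausibility flag (stored as an attribute).
#' @return An `r_peak_series` data frame.
#' @export
r_peak_series <- function(t, idx, fs, usable = TRUE) {
  structure(data.frame(t = t, idx = idx),
            fs = fs, usable = usable,
            class = c("r_peak_series", "data.frame"))
}

#' Build the cleaned RR series with ectopic rejection
#'
#' Successive R-peak differences give the RR intervals; any interval
#' deviating by more than 20% (strictly) from the mean of its up-to-5
#' nearest accepted neighbours (excluding itself) is removed as ectopic in
#' a single left-to-right pass, leaving a gap flag that breaks
#' successive-difference chains.
#'
#' @param peaks an `r_peak_series` with at least 3 peaks.
#' @param tol relative deviation bound (default 0.20).
#' @param k_neighbours neighbours used for the local mean (default 5).
#' @return An `rr_series` (`t` interval start s, `rri` ms, `gap`), with
#'   attributes `n_removed` and `usable` (`FALSE` when more than half the
#'   intervals were removed).
#' @export
clean_rr <- function(peaks, tol = 0.20, k_neighbours = 5) {
  if (nrow(peaks) < 3) stop("clean_rr: need at least 3 peaks")
  rri <- diff(peaks$t) * 1000
  tt <- peaks$t[-nrow(peaks)]
  m <- length(rri)
  rejected <- rep(FALSE, m)
  for (i in seq_len(m)) {
    pool <- setdiff(which(!rejected), i)
    if (!length(pool)) next
    nb <- pool[order(abs(pool - i))][seq_len(min(k_neighbours, length(pool)))]
    lm <- mean(rri[nb])
    if (abs(rri[i] - lm) > tol * lm) rejected[i] <- TRUE
  }
  keep <- which(!rejected)
  gap <- c(TRUE, diff(keep) != 1L)
  out <- rr_series(t = tt[keep], rri = rri[keep], gap = gap)
  attr(out, "n_removed") <- sum(rejected)
  attr(out, "usable") <- sum(rejected) <= 0.5 * m
  out
}

#' Time-domain HRV features
#'
#' Mean RR, SDNN (sample SD, N-1 denominator) and RMSSD (root mean square
#' of successive differences over gap-free consecutive pairs only; gaps
#' from ectopic removal never contribute fabricated differences).
#'
#' @param rr an `rr_series` with >= 2 intervals.
#' @return List: `MeanRR`, `SDNN`, `RMSSD` (ms) and `flags` (contains
#'   "rmssd_unreliable" when fewer than 2 gap-free pairs exist; RMSSD is
#'   then 0).
#' @export
time_domain_hrv <- function(rr) {
  if (nrow(rr) < 2) stop("time_domain_hrv: need at least 2 intervals")
  flags <- character(0)
  mean_rr <- mean(rr$rri)
  sdnn <- stats::sd(rr$rri)
  pair_ok <- !rr$gap[-1]
  diffs <- diff(rr$rri)[pair_ok]
  if (length(diffs) >= 2) {
    rmssd <- sqrt(mean(diffs^2))
  } else {
    rmssd <- 0
    flags <- c(flags, "rmssd_unreliable")
  }
  list(MeanRR = mean_rr, SDNN = sdnn, RMSSD = rmssd, flags = flags)
}

#' Frequency-domain HRV (LF, HF, LF/HF)
#'
#' The unevenly sampled tachogram is cubic-spline interpolated onto a
#' uniform 4 Hz grid, linearly detrended, Hann-tapered, and turned into a
#' one-sided periodogram; band powers are trapezoid-integrated over the LF
#' (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands.
#'
#' @param rr an `rr_series` spanning at least `min_span` seconds.
#' @param resample_fs tachogram resampling rate, Hz (default 4).
#' @param min_span minimum usable span, s (default 30).
#' @return List: `LF`, `HF` (ms^2), `LFHF`, `flags`. A zero HF power gives
#'   `LFHF = 1e6` with flag "hf_zero" instead of dividing by zero; a short
#'   span yields zeros with flag "short_span".
#' @export
freq_domain_hrv <- function(rr, resample_fs = 4, min_span = 30) {
  span <- (rr$t[nrow(rr)] + rr$rri[nrow(rr)] / 1000) - rr$t[1]
  if (nrow(rr) < 4 || span < min_span) {
    return(list(LF = 0, HF = 0, LFHF = 0, flags = "short_span"))
  }
  grid <- seq(rr$t[1], rr$t[nrow(rr)], by = 1 / resample_fs)
  tach <- stats::spline(rr$t, rr$rri, xout = grid, method = "natural")$y
  tach <- stats::residuals(stats::lm(tach ~ grid)) # linear detrend
  n <- length(tach)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1))) # Hann
  xw <- tach * w
  spec <- abs(stats::fft(xw))^2 / (resample_fs * sum(w^2))
  nf <- floor(n / 2) + 1L
  freq <- (seq_len(nf) - 1L) * resample_fs / n
  psd <- spec[seq_len(nf)]
  psd[c(-1, -nf)] <- 2 * psd[c(-1, -nf)] # one-sided

  band_power <- function(lo, hi) {
    sel <- which(freq >= lo & freq < hi)
    if (length(sel) < 2) return(0)
    sum(diff(freq[sel]) * (psd[sel[-1]] + psd[sel[-length(sel)]]) / 2)
  }
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.40)
  flags <- character(0)
  if (hf <= 0) {
    lfhf <- 1e6
    flags <- c(flags, "hf_zero")
  } else {
    lfhf <- lf / hf
  }
  list(LF = lf, HF = hf, LFHF = lfhf, flags = flags)
}

#' All four cardiac features for one window
#'
#' Subsets the R-peak series to the window, builds the cleaned RR series
#' and computes MeanRR, SDNN, RMSSD and LF/HF. Windows with fewer than 3
#' peaks, an unusable RR series, or an implausible within-window heart
#' rate are flagged unusable.
#'
#' @param peaks an `r_peak_series` for the whole recording.
#' @param window half-open window `[t0, t1)` in s.
#' @param hr_bounds plausible heart-rate range, bpm.
#' @return Named list: MeanRR, SDNN, RMSSD, LFHF, flags, usable.
#' @export
cardiac_features <- function(peaks, window, hr_bounds = c(40, 180)) {
  sel <- peaks$t >= window[1] & peaks$t < window[2]
  sub <- peaks[sel, , drop = FALSE]
  empty <- list(MeanRR = 0, SDNN = 0, RMSSD = 0, LFHF = 0,
                flags = "cardiac_unusable", usable = FALSE)
  if (nrow(sub) < 3) return(empty)
  bpm <- nrow(sub) / (window[2] - window[1]) * 60
  if (bpm < hr_bounds[1] || bpm > hr_bounds[2]) return(empty)
  rr <- clean_rr(r_peak_series(sub$t, sub$idx, attr(peaks, "fs")))
  if (!attr(rr, "usable") || nrow(rr) < 2) return(empty)
  td <- time_domain_hrv(rr)
  fd <- freq_domain_hrv(rr)
  list(MeanRR = td$MeanRR, SDNN = td$SDNN, RMSSD = td$RMSSD,
       LFHF = fd$LFHF, flags = unique(c(td$flags, fd$flags)),
       usable = TRUE)
}
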