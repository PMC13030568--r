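test_that("wavelet denoising has the contracted algebraic properties", {
  # zero in -> zero out (linearity)
  z <- ecg_trace(t = (0:2047) / 512, v = rep(0, 2048), fs = 512)
  expect_true(all(wavelet_denoise(z)$v == 0))

  # soft threshold: sub-threshold coefficients become exactly 0
  d <- c(-2, -0.5, 0, 0.5, 2)
  out <- fatiguefusion:::soft_threshold(d, lambda = 1)
  expect_equal(out, c(-1, 0, 0, 0, 1))

  # DWT round-trip is exact (orthonormal periodized filter bank)
  set.seed(1)
  x <- stats::rnorm(1024)
  dec <- fatiguefusion:::dwt_forward(x, 8)
  expect_equal(fatiguefusion:::dwt_inverse(dec), x, tolerance = 1e-10)
  # Parseval: energy preserved across the decomposition
  expect_equal(sum(x^2), sum(dec$approx^2) + sum(unlist(dec$details)^2),
               tolerance = 1e-8)

  # non-dyadic lengths are padded and unpadded transparently
  odd <- ecg_trace(t = (0:2999) / 512, v = stats::rnorm(3000), fs = 512)
  expect_length(wavelet_denoise(odd)$v, 3000)
})

test_that("denoising removes most of a 0.3 mV baseline drift", {
  p <- alert_regime()
  rrg <- gen_rr_series(p, 60, seed = 11)
  eg <- gen_ecg(rrg, duration = 61,
                noise = list(baseline_amp = 0.3, powerline_amp = 0,
                             white_sd = 0.02), seed = 12)
  den <- wavelet_denoise(eg$ecg)
  amp <- function(v, t) {
    X <- cbind(sin(2 * pi * 0.2 * t), cos(2 * pi * 0.2 * t))
    cf <- coef(stats::lm(v ~ X))
    sqrt(cf[2]^2 + cf[3]^2)
  }
  before <- amp(eg$ecg$v, eg$ecg$t)
  after <- amp(den$v, den$t)
  expect_gte(1 - after / before, 0.80)

  # near-idempotence: a second pass changes little relative to the first
  den2 <- wavelet_denoise(den)
  change1 <- sqrt(mean((den$v - eg$ecg$v)^2))
  change2 <- sqrt(mean((den2$v - den$v)^2))
  expect_lt(change2, 0.05 * change1)
})

test_that("R-peak detection is near-perfect on clean synthetic ECG", {
  p <- alert_regime()
  sens <- prec <- rmssd_err <- numeric(20)
  for (s in 1:20) {
    rrg <- gen_rr_series(p, 60, seed = s)
    eg <- gen_ecg(rrg, duration = 61,
                  noise = list(baseline_amp = 0, powerline_amp = 0,
                               white_sd = 0), seed = 500 + s)
    pk <- pan_tompkins(wavelet_denoise(eg$ecg))
    m <- vapply(eg$truth$r_times, function(tt) min(abs(pk$t - tt)),
                numeric(1))
    mp <- vapply(pk$t, function(tt) min(abs(eg$truth$r_times - tt)),
                 numeric(1))
    sens[s] <- mean(m < 0.05)
    prec[s] <- mean(mp < 0.05)
    td <- time_domain_hrv(clean_rr(pk))
    rmssd_err[s] <- abs(td$RMSSD - rrg$truth$rmssd) / rrg$truth$rmssd
  }
  expect_gte(mean(sens), 0.99)
  expect_gte(mean(prec), 0.99)
  expect_lte(max(rmssd_err), 0.10)
})

test_that("implausible or degenerate traces are flagged, not crashed", {
  t <- (0:(512 * 10 - 1)) / 512
  zero <- ecg_trace(t = t, v = rep(0, length(t)), fs = 512)
  pk <- pan_tompkins(zero)
  expect_equal(nrow(pk), 0)
  expect_false(attr(pk, "usable"))

  set.seed(2)
  noise <- ecg_trace(t = t, v = stats::rnorm(length(t), 0, 0.3), fs = 512)
  pk2 <- pan_tompkins(noise)
  # white noise must not yield a plausible 40-180 bpm detection train
  expect_false(attr(pk2, "usable"))

  short <- ecg_trace(t = (0:511) / 512, v = stats::rnorm(512), fs = 512)
  expect_error(pan_tompkins(short), "5 s")
})

test_that("ectopic rejection implements the 20% local-mean rule", {
  mk_peaks <- function(rri_ms) {
    tt <- cumsum(c(0, rri_ms)) / 1000
    r_peak_series(t = tt, idx = round(tt * 512), fs = 512)
  }
  # 1200 among 800s deviates 50% -> removed, gap flagged
  rr <- clean_rr(mk_peaks(c(800, 800, 800, 1200, 800)))
  expect_equal(nrow(rr), 4)
  expect_equal(attr(rr, "n_removed"), 1)
  expect_true(any(rr$gap[-1]))

  # constant series unchanged
  rr2 <- clean_rr(mk_peaks(rep(800, 10)))
  expect_equal(attr(rr2, "n_removed"), 0)
  expect_equal(rr2$rri, rep(800, 10))

  # exactly +20% of the local mean is kept (strict inequality)
  rr3 <- clean_rr(mk_peaks(c(800, 800, 800, 800, 800, 960)))
  expect_equal(attr(rr3, "n_removed"), 0)

  expect_error(clean_rr(mk_peaks(800)), "3 peaks")
})

test_that("time-domain HRV matches hand-worked cases and a naive oracle", {
  expect_hrv <- function(rri, mean_rr, sdnn, rmssd) {
    rr <- rr_series(t = cumsum(c(0, rri[-length(rri)])) / 1000, rri = rri)
    td <- time_domain_hrv(rr)
    expect_equal(td$MeanRR, mean_rr)
    expect_equal(td$SDNN, sdnn, tolerance = 1e-12)
    expect_equal(td$RMSSD, rmssd, tolerance = 1e-12)
  }
  expect_hrv(rep(800, 10), 800, 0, 0)
  expect_hrv(c(780, 800, 820), 800, 20, 20)
  expect_hrv(rep(c(790, 810), 5), 800, stats::sd(rep(c(790, 810), 5)), 20)

  # naive two-pass oracle on random series
  set.seed(3)
  for (i in 1:20) {
    rri <- stats::rnorm(50, 800, 40)
    rr <- rr_series(t = cumsum(c(0, rri[-50])) / 1000, rri = rri)
    td <- time_domain_hrv(rr)
    mu <- sum(rri) / 50
    sdnn_ref <- sqrt(sum((rri - mu)^2) / 49)
    rmssd_ref <- sqrt(sum((rri[-1] - rri[-50])^2) / 49)
    expect_equal(td$SDNN, sdnn_ref, tolerance = 1e-9)
    expect_equal(td$RMSSD, rmssd_ref, tolerance = 1e-9)
  }

  # gaps break successive-difference chains
  rri <- c(800, 800, 1200, 800, 800)
  rr <- rr_series(t = cumsum(c(0, rri[-5])) / 1000, rri = rri,
                  gap = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  td <- time_domain_hrv(rr)
  # only pairs (1,2), (3,4), (4,5) count: diffs 0, -400, 0
  expect_equal(td$RMSSD, sqrt(mean(c(0, -400, 0)^2)))
})

test_that("spectral HRV separates known LF and HF tones", {
  mk_rr <- function(lf, hf, seed) {
    p <- alert_regime()
    p$lf_amp <- lf
    p$hf_amp <- hf
    p$rmssd_target <- 1
    gen_rr_series(p, 120, seed = seed)$rr
  }
  # pure 0.25 Hz tone: HF dominates
  fd_hf <- freq_domain_hrv(mk_rr(0, 40, 21))
  expect_lt(fd_hf$LFHF, 0.2)
  expect_gte(fd_hf$HF / (fd_hf$HF + fd_hf$LF), 0.9)
  # pure 0.10 Hz tone: LF dominates
  fd_lf <- freq_domain_hrv(mk_rr(40, 0, 22))
  expect_gt(fd_lf$LFHF, 5)
  # equal tones: ratio near 1 (leakage tolerated)
  fd_eq <- freq_domain_hrv(mk_rr(30, 30, 23))
  expect_gte(fd_eq$LFHF, 0.5)
  expect_lte(fd_eq$LFHF, 2)

  # degenerate short span is flagged rather than crashing
  short <- rr_series(t = c(0, 0.8, 1.6), rri = rep(800, 3))
  expect_equal(freq_domain_hrv(short)$flags, "short_span")
})

test_that("windowed cardiac features flag unusable windows", {
  p <- alert_regime()
  rrg <- gen_rr_series(p, 65, seed = 31)
  eg <- gen_ecg(rrg, duration = 66, seed = 32)
  pk <- pan_tompkins(wavelet_denoise(eg$ecg))
  cf <- cardiac_features(pk, c(0, 60))
  expect_true(cf$usable)
  expect_gt(cf$MeanRR, 600)
  expect_lt(cf$MeanRR, 900)
  # a window with almost no peaks is unusable
  cf2 <- cardiac_features(pk, c(64, 124))
  expect_false(cf2$usable)
})
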