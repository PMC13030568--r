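test_that("blink repair partitions zero-pupil runs by duration", {
  # 200 ms run -> exactly one blink, gaze interpolated, pupil stays closed
  g <- make_gaze_with_gap(200)
  rep <- repair_blinks(g)
  expect_equal(sum(rep$events$kind == "blink"), 1)
  expect_equal(sum(rep$events$kind == "closure"), 0)
  expect_true(all(rep$stream$x == 1))
  expect_true(any(rep$stream$closed))

  # 40 ms run -> dropout: interpolated, not a blink
  g <- make_gaze_with_gap(40)
  rep <- repair_blinks(g)
  expect_equal(sum(rep$events$kind == "blink"), 0)
  expect_equal(sum(rep$events$kind == "dropout"), 1)
  expect_true(all(rep$stream$pupil > 0))

  # 900 ms run -> closure, samples invalidated
  g <- make_gaze_with_gap(900)
  rep <- repair_blinks(g)
  expect_equal(sum(rep$events$kind == "closure"), 1)
  expect_equal(sum(rep$events$kind == "blink"), 0)
  expect_true(any(!rep$stream$valid))

  # all-zero pupil -> unusable, not interpolated
  g$pupil[] <- 0
  expect_warning(rep <- repair_blinks(g), "unusable")
  expect_true(attr(rep$stream, "unusable"))
})

test_that("I-VT velocity boundary follows the 30 deg/s rule", {
  fs <- 100
  # displacement per 10 ms step: 0.2 deg -> 20 deg/s (fixation),
  # 0.5 deg -> 50 deg/s (saccade), 0.3 deg -> exactly 30 deg/s (saccade)
  for (case in list(c(0.2, 0), c(0.5, 1), c(0.3, 1))) {
    step <- case[1]
    n <- 60
    g <- gaze_stream(t = (seq_len(n) - 1) / fs, x = step * (seq_len(n) - 1),
                     y = rep(0, n), pupil = rep(3, n), fs = fs)
    g$closed <- FALSE
    ev <- ivt_classify(g)
    if (case[2] == 0) {
      expect_true(all(ev$kind == "fixation"))
    } else {
      expect_true(all(ev$kind == "saccade"))
    }
  }
})

test_that("I-VT yields a clean partition and splits on blinks", {
  s <- make_two_fixation_stream()
  s$closed <- FALSE
  ev <- ivt_classify(s)
  expect_equal(sum(ev$kind == "fixation"), 2)
  # events tile the stream: non-overlapping and ordered
  expect_true(all(diff(ev$onset) > 0))
  expect_true(all(ev$offset > ev$onset))
  expect_true(all(utils::head(ev$offset, -1) <= utils::tail(ev$onset, -1) +
                    1e-9))

  # a blink in the middle of a steady fixation splits it in two
  g <- make_gaze_with_gap(200, dur_s = 4)
  po <- parse_ocular(g)
  expect_equal(sum(po$events$kind == "fixation"), 2)

  short <- gaze_stream(t = 0, x = 0, y = 0, pupil = 3, fs = 100)
  short$closed <- FALSE
  expect_warning(ev0 <- ivt_classify(short), "2 usable")
  expect_equal(nrow(ev0), 0)
})

test_that("scripted fixations are recovered with small onset error", {
  p <- alert_regime()
  p$blink_rate <- 0
  p$closure_rate <- 0
  hits <- total <- 0
  for (s in 1:5) {
    gg <- gen_gaze_stream(p, aoi_grid(), 60, seed = s)
    fx <- parse_ocular(gg$gaze)$events
    fx <- fx[fx$kind == "fixation", ]
    tr <- gg$truth$fixations
    hits <- hits + sum(vapply(tr$onset, function(o) {
      any(abs(fx$onset - o) <= 0.020)
    }, logical(1)))
    total <- total + nrow(tr)
  }
  expect_gte(hits / total, 0.95)
})

test_that("basic ocular features match closed-form window arithmetic", {
  fs <- 100
  n <- 60 * fs
  stream <- gaze_stream(t = (seq_len(n) - 1) / fs, x = rep(0, n),
                        y = rep(0, n), pupil = rep(3, n), fs = fs)
  stream$closed <- c(rep(TRUE, 6 * fs), rep(FALSE, n - 6 * fs))
  ev <- data.frame(
    kind = c(rep("blink", 5), rep("fixation", 3)),
    onset = c(seq(1, 5), c(10, 20, 30)),
    offset = c(seq(1, 5) + 0.2, c(10, 20, 30) + 0.4),
    duration_ms = c(rep(200, 5), rep(400, 3)),
    cx = 0, cy = 0)
  f <- basic_ocular_features(stream, ev, c(0, 60))
  expect_equal(f$PERCLOS, 0.10)      # 6 s closed of 60 s
  expect_equal(f$BF, 5)              # 5 blinks / min
  expect_equal(f$MBD, 200)
  expect_equal(f$MFD, 400)
  expect_equal(f$FF, 3)
  expect_equal(f$PDV, 0)             # constant pupil

  # adding closure time never decreases PERCLOS
  stream2 <- stream
  stream2$closed[(50 * fs):(55 * fs)] <- TRUE
  f2 <- basic_ocular_features(stream2, ev, c(0, 60))
  expect_gte(f2$PERCLOS, f$PERCLOS)

  # zero fixations -> MFD 0 with quality flag; zero blinks -> MBD 0
  f3 <- basic_ocular_features(stream, ev[ev$kind == "blink", ], c(0, 60))
  expect_equal(f3$MFD, 0)
  expect_true("no_fixations" %in% f3$flags)
  f4 <- basic_ocular_features(stream, ev[ev$kind == "fixation", ], c(0, 60))
  expect_equal(f4$MBD, 0)
})

test_that("stationary gaze entropy matches hand-computed cases", {
  grid <- aoi_grid(4, 8, c(-60, 60), c(-15, 15))
  centres <- expand.grid(col = 1:8, row = 1:4)
  cx <- -60 + (centres$col - 0.5) * 15
  cy <- -15 + (centres$row - 0.5) * 7.5

  # uniform over all 32 cells -> log2(32) = 5 bits
  fx <- data.frame(cx = cx, cy = cy)
  expect_equal(stationary_gaze_entropy(fx, grid), 5)

  # all in one cell -> 0
  fx1 <- data.frame(cx = rep(cx[1], 7), cy = rep(cy[1], 7))
  expect_equal(stationary_gaze_entropy(fx1, grid), 0)

  # shares (0.75, 0.25) -> 0.8113 bits
  fx2 <- data.frame(cx = c(rep(cx[1], 3), cx[2]),
                    cy = c(rep(cy[1], 3), cy[2]))
  expect_equal(stationary_gaze_entropy(fx2, grid),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)

  e0 <- stationary_gaze_entropy(fx1[0, ], grid)
  expect_equal(as.numeric(e0), 0)
  expect_identical(attr(e0, "quality"), "no_fixations")
})

test_that("transition gaze entropy matches closed-form chain cases", {
  grid <- aoi_grid(2, 2, c(0, 2), c(0, 2))
  cc <- rbind(c(0.5, 0.5), c(1.5, 0.5), c(0.5, 1.5), c(1.5, 1.5))

  # strict alternation A-B-A-B: all rows deterministic -> 0 bits
  alt <- cc[rep(c(1, 2), 10), ]
  fx <- data.frame(cx = alt[, 1], cy = alt[, 2])
  expect_equal(transition_gaze_entropy(fx, grid), 0)

  # a cyclic walk 1-2-3-4-1-2-3-4-... is deterministic -> 0 bits
  cyc <- cc[rep(1:4, 6), ]
  expect_equal(transition_gaze_entropy(
    data.frame(cx = cyc[, 1], cy = cyc[, 2]), grid), 0)

  # weighted-row formula, hand case: p_i = (.5, .5) with rows (.9, .1)
  # and (.5, .5) evaluates to 0.7345 bits
  h_expected <- 0.5 * (-(0.9 * log2(0.9) + 0.1 * log2(0.1))) + 0.5 * 1
  expect_equal(h_expected, 0.7345, tolerance = 1e-4)

  e0 <- transition_gaze_entropy(data.frame(cx = 0.5, cy = 0.5), grid)
  expect_equal(as.numeric(e0), 0)
})

test_that("transition entropy equals an independent hand count on walks", {
  grid <- aoi_grid(3, 3, c(0, 3), c(0, 3))
  set.seed(7)
  for (rep_i in 1:10) {
    walk <- sample(1:9, 40, replace = TRUE)
    cx <- (walk - 1) %% 3 + 0.5
    cy <- (walk - 1) %/% 3 + 0.5
    fx <- data.frame(cx = cx, cy = cy)
    # independent computation: tabulate transitions, loop explicitly
    from <- walk[-length(walk)]
    to <- walk[-1]
    h <- 0
    n_tr <- length(from)
    for (i in unique(from)) {
      sel <- from == i
      p_i <- sum(sel) / n_tr
      row_h <- 0
      for (j in unique(to[sel])) {
        p_ij <- sum(sel & to == j) / sum(sel)
        row_h <- row_h - p_ij * log2(p_ij)
      }
      h <- h + p_i * row_h
    }
    expect_equal(transition_gaze_entropy(fx, grid), h, tolerance = 1e-12)
  }
})

test_that("entropies stay within [0, log2 K] on random fixation sets", {
  grid <- aoi_grid()
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    fx <- data.frame(cx = stats::runif(n, -60, 60),
                     cy = stats::runif(n, -15, 15))
    sge <- stationary_gaze_entropy(fx, grid)
    tge <- transition_gaze_entropy(fx, grid)
    expect_gte(as.numeric(sge), 0)
    expect_lte(as.numeric(sge), log2(32))
    expect_gte(as.numeric(tge), 0)
    expect_lte(as.numeric(tge), log2(32) + 1e-9)
  }
})
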