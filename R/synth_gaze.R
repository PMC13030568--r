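#' Area-of-interest grid
#'
#' Tiles the display bounds (degrees of visual angle) into `rows x cols`
#' half-open cells; the right/top edges belong to the last cell. The
#' default 4 x 8 grid spans a three-screen panoramic view.
#'
#' @param rows,cols grid dimensions (product >= 2).
#' @param xlim,ylim screen bounds in degrees.
#' @return An `aoi_grid` object.
#' @export
aoi_grid <- function(rows = 4, cols = 8, xlim = c(-60, 60), ylim = c(-15, 15)) {
  if (rows * cols < 2) stop("aoi_grid: grid must have at least 2 cells")
  stopifnot(xlim[2] > xlim[1], ylim[2] > ylim[1])
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 xlim = xlim, ylim = ylim),
            class = "aoi_grid")
}

n_cells <- function(grid) grid$rows * grid$cols

#' Map gaze coordinates to AOI cell indices
#'
#' @param grid an [aoi_grid()].
#' @param x,y coordinates in degrees.
#' @return Integer cell index in `1..rows*cols` (row-major); points outside
#'   the bounds are clamped to the nearest cell.
#' @export
aoi_cell <- function(grid, x, y) {
  cw <- (grid$xlim[2] - grid$xlim[1]) / grid$cols
  ch <- (grid$ylim[2] - grid$ylim[1]) / grid$rows
  ci <- pmin(pmax(floor((x - grid$xlim[1]) / cw), 0), grid$cols - 1L)
  ri <- pmin(pmax(floor((y - grid$ylim[1]) / ch), 0), grid$rows - 1L)
  as.integer(ri * grid$cols + ci + 1L)
}

aoi_cell_centre <- function(grid, cell) {
  cw <- (grid$xlim[2] - grid$xlim[1]) / grid$cols
  ch <- (grid$ylim[2] - grid$ylim[1]) / grid$rows
  ci <- (cell - 1L) %% grid$cols
  ri <- (cell - 1L) %/% grid$cols
  cbind(x = grid$xlim[1] + (ci + 0.5) * cw,
        y = grid$ylim[1] + (ri + 0.5) * ch)
}

# Row-stochastic AOI transition kernel: mixture of the uniform chain
# (weight = concentration) and a local chain putting 60% mass on the
# current cell and 40% spread over its 4-neighbours.
aoi_transition_kernel <- function(grid, concentration) {
  K <- n_cells(grid)
  P <- matrix(concentration / K, K, K)
  for (cell in seq_len(K)) {
    ci <- (cell - 1L) %% grid$cols
    ri <- (cell - 1L) %/% grid$cols
    nb <- c(
      if (ci > 0) cell - 1L,
      if (ci < grid$cols - 1L) cell + 1L,
      if (ri > 0) cell - grid$cols,
      if (ri < grid$rows - 1L) cell + grid$cols
    )
    P[cell, cell] <- P[cell, cell] + (1 - concentration) * 0.6
    P[cell, nb] <- P[cell, nb] + (1 - concentration) * 0.4 / length(nb)
  }
  P
}

#' Generate a synthetic gaze stream
#'
#' Simulates a 100 Hz eye-tracking record: fixation targets follow a Markov
#' chain over AOI cells (dispersion set by `aoi_concentration`), fixation
#' durations are log-normal, saccades are ballistic (constant velocity 200
#' deg/s, well above the 30 deg/s I-VT threshold), pupil diameter is an
#' AR(1) process around `pupil_base`, and Poisson-scheduled blinks
#' (75-500 ms) and long closures (> 500 ms) zero the pupil and invalidate
#' the gaze coordinates.
#'
#' @param params a [regime_params()] object.
#' @param grid an [aoi_grid()] with >= 2 cells.
#' @param duration recording length, s (>= 60).
#' @param fs sampling rate, Hz (default 100).
#' @param seed optional integer seed.
#' @return List with `gaze` (a `gaze_stream` data frame: `t`, `x`, `y`,
#'   `pupil`, `valid`) and `truth` (fixation table with onset/offset/cell,
#'   blink and closure tables, and the empirical per-recording PERCLOS,
#'   blink stats and fixation stats).
#' @export
gen_gaze_stream <- function(params, grid = aoi_grid(), duration, fs = 100,
                            seed = NULL) {
  stopifnot(inherits(params, "regime_params"), inherits(grid, "aoi_grid"))
  if (n_cells(grid) < 2) stop("gen_gaze_stream: grid must have >= 2 cells")
  if (duration < 60) stop("gen_gaze_stream: duration must be >= 60 s")
  if (!is.null(seed)) set.seed(seed)

  K <- n_cells(grid)
  P <- aoi_transition_kernel(grid, params$aoi_concentration)

  # --- scripted fixation/saccade event sequence ---------------------------
  n_fix_max <- ceiling(duration * 1000 / (params$fix_dur_mean * 0.5)) + 4L
  cells <- integer(0)
  onsets <- numeric(0)
  offsets <- numeric(0)
  cxs <- numeric(0)
  cys <- numeric(0)
  cell <- sample.int(K, 1)
  t <- 0
  sdlog <- 0.35
  cw <- (grid$xlim[2] - grid$xlim[1]) / grid$cols
  ch <- (grid$ylim[2] - grid$ylim[1]) / grid$rows
  pos_prev <- NULL
  sac_from <- numeric(0) # saccade start times (for truth)
  while (t < duration && length(cells) < n_fix_max) {
    dur <- stats::rlnorm(1, log(params$fix_dur_mean), sdlog) / 1000
    dur <- max(dur, 0.12)
    centre <- aoi_cell_centre(grid, cell)
    px <- centre[1, "x"] + stats::rnorm(1, 0, cw / 8)
    py <- centre[1, "y"] + stats::rnorm(1, 0, ch / 8)
    cells <- c(cells, cell)
    onsets <- c(onsets, t)
    offsets <- c(offsets, min(t + dur, duration))
    cxs <- c(cxs, px)
    cys <- c(cys, py)
    t <- t + dur
    # saccade to next target at 200 deg/s (>= 1 sample, <= 80 ms)
    nxt <- sample.int(K, 1, prob = P[cell, ])
    centre2 <- aoi_cell_centre(grid, nxt)
    amp <- sqrt(sum((centre2 - centre)^2))
    sdur <- min(max(amp / 200, 1.5 / fs), 0.08)
    sac_from <- c(sac_from, t)
    t <- t + sdur
    cell <- nxt
  }
  fix <- data.frame(onset = onsets, offset = offsets, cell = cells,
                    cx = cxs, cy = cys)

  # --- sample-level trajectories ------------------------------------------
  n <- floor(duration * fs)
  tvec <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  y <- numeric(n)
  # fixation samples: centroid + micro-jitter (well below 30 deg/s)
  jit <- 0.03
  seg_start <- c(fix$onset, duration)
  idx_fix <- findInterval(tvec, fix$onset)
  in_fix <- idx_fix >= 1 & tvec < fix$offset[pmax(idx_fix, 1)]
  x[in_fix] <- fix$cx[idx_fix[in_fix]] + stats::rnorm(sum(in_fix), 0, jit)
  y[in_fix] <- fix$cy[idx_fix[in_fix]] + stats::rnorm(sum(in_fix), 0, jit)
  # saccade samples: linear interpolation between consecutive centroids
  sac <- which(!in_fix)
  if (length(sac)) {
    k <- pmax(idx_fix[sac], 1L)
    tail_ <- k >= nrow(fix)
    k2 <- pmin(k + 1L, nrow(fix))
    t0 <- fix$offset[k]
    t1 <- fix$onset[k2]
    a <- ifelse(t1 > t0, (tvec[sac] - t0) / (t1 - t0), 1)
    a <- pmin(pmax(a, 0), 1)
    a[tail_] <- 1
    x[sac] <- fix$cx[k] + a * (fix$cx[k2] - fix$cx[k])
    y[sac] <- fix$cy[k] + a * (fix$cy[k2] - fix$cy[k])
  }

  # --- pupil AR(1) --------------------------------------------------------
  phi <- 0.98
  innov <- stats::rnorm(n, 0, params$pupil_sd * sqrt(1 - phi^2))
  pupil <- params$pupil_base +
    as.numeric(stats::filter(innov, phi, method = "recursive"))

  # --- blinks and long closures ------------------------------------------
  draw_events <- function(rate_per_min, med_ms, sdlog, lo_ms, hi_ms) {
    n_ev <- stats::rpois(1, rate_per_min * duration / 60)
    if (n_ev == 0) {
      return(data.frame(onset = numeric(0), dur = numeric(0)))
    }
    onset <- sort(stats::runif(n_ev, 0, duration))
    dur <- pmin(pmax(stats::rlnorm(n_ev, log(med_ms), sdlog), lo_ms),
                hi_ms) / 1000
    data.frame(onset = onset, dur = dur)
  }
  blinks <- draw_events(params$blink_rate, params$blink_dur_mean, 0.25,
                        80, 480)
  closures <- draw_events(params$closure_rate, 900, 0.3, 550, 2200)
  blinks$kind <- rep("blink", nrow(blinks))
  closures$kind <- rep("closure", nrow(closures))
  ev <- rbind(blinks, closures)
  if (nrow(ev) > 0) {
    ev <- ev[order(ev$onset), , drop = FALSE]
    # drop events overlapping an earlier one
    keep <- rep(TRUE, nrow(ev))
    last_end <- -Inf
    for (i in seq_len(nrow(ev))) {
      if (ev$onset[i] <= last_end + 0.05) {
        keep[i] <- FALSE
      } else {
        last_end <- ev$onset[i] + ev$dur[i]
      }
    }
    ev <- ev[keep, , drop = FALSE]
    ev$offset <- pmin(ev$onset + ev$dur, duration)
    for (i in seq_len(nrow(ev))) {
      sel <- tvec >= ev$onset[i] & tvec < ev$offset[i]
      pupil[sel] <- 0
      x[sel] <- 0
      y[sel] <- 0
    }
  } else {
    ev$offset <- numeric(0)
  }
  closed <- pupil == 0

  gaze <- gaze_stream(t = tvec, x = x, y = y, pupil = pmax(pupil, 0),
                      valid = !closed, fs = fs)
  truth <- list(
    fixations = fix,
    blinks = ev[ev$kind == "blink", c("onset", "offset")],
    closures = ev[ev$kind == "closure", c("onset", "offset")],
    perclos = sum(closed) / n,
    params = params
  )
  list(gaze = gaze, truth = truth)
}

#' Gaze stream container
#'
#' @param t sample times, s (uniform, nominally 100 Hz).
#' @param x,y gaze angles, degrees.
#' @param pupil pupil diameter, mm (0 = closed/lost).
#' @param valid per-sample validity (default `pupil > 0`).
#' @param fs sampling rate, Hz (inferred from `t` when omitted).
#' @return A `gaze_stream` data frame.
#' @export
gaze_stream <- function(t, x, y, pupil, valid = NULL, fs = NULL) {
  stopifnot(length(t) == length(x), length(x) == length(y),
            length(y) == length(pupil), all(pupil >= 0))
  if (is.null(valid)) valid <- pupil > 0
  if (is.null(fs)) fs <- 1 / stats::median(diff(t))
  structure(data.frame(t = t, x = x, y = y, pupil = pupil, valid = valid),
            fs = fs, class = c("gaze_stream", "data.frame"))
}

gaze_fs <- function(stream) attr(stream, "fs")
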