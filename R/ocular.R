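#' Repair blink artifacts in a gaze stream
#'
#' Zero-pupil runs are partitioned by duration: runs shorter than
#' `blink_bounds[1]` (default 75 ms) are tracker dropouts whose x, y and
#' pupil values are linearly interpolated; runs within `blink_bounds`
#' (75-500 ms) are normal blinks whose gaze coordinates are interpolated to
#' preserve trajectory continuity while the pupil remains recorded as
#' closed (so PERCLOS still sees the closure); runs longer than
#' `blink_bounds[2]` are long eyelid closures whose samples are marked
#' invalid and excluded from fixation parsing.
#'
#' @param stream a `gaze_stream` data frame (`t`, `x`, `y`, `pupil`,
#'   `valid`).
#' @param blink_bounds numeric length-2, blink duration bounds in ms.
#' @return List with `stream` (repaired; gains a logical `closed` column)
#'   and `events` (data frame: kind in blink/closure/dropout, onset,
#'   offset, duration_ms). If the pupil is zero throughout, the stream is
#'   flagged unusable (`attr(, "unusable")`) and returned uninterpolated.
#' @export
repair_blinks <- function(stream, blink_bounds = c(75, 500)) {
  stopifnot(nrow(stream) > 0)
  fs <- gaze_fs(stream)
  dt <- 1 / fs
  zero <- stream$pupil == 0

  if (all(zero)) {
    stream$closed <- TRUE
    stream$valid <- FALSE
    attr(stream, "unusable") <- TRUE
    warning("repair_blinks: pupil is zero throughout; stream unusable")
    return(list(stream = stream, events = ocular_event_frame()))
  }

  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  events <- list()
  stream$closed <- FALSE

  interp_cols <- function(stream, i0, i1, cols) {
    lo <- i0 - 1L
    hi <- i1 + 1L
    n <- nrow(stream)
    for (cl in cols) {
      v0 <- if (lo >= 1L) stream[[cl]][lo] else stream[[cl]][hi]
      v1 <- if (hi <= n) stream[[cl]][hi] else stream[[cl]][lo]
      a <- seq_len(i1 - i0 + 1L) / (i1 - i0 + 2L)
      stream[[cl]][i0:i1] <- v0 + a * (v1 - v0)
    }
    stream
  }

  for (k in runs) {
    i0 <- starts[k]
    i1 <- ends[k]
    dur_ms <- (i1 - i0 + 1L) * dt * 1000
    onset <- stream$t[i0]
    offset <- stream$t[i1] + dt
    if (dur_ms < blink_bounds[1]) {
      stream <- interp_cols(stream, i0, i1, c("x", "y", "pupil"))
      stream$valid[i0:i1] <- TRUE
      kind <- "dropout"
    } else if (dur_ms <= blink_bounds[2]) {
      stream <- interp_cols(stream, i0, i1, c("x", "y"))
      stream$closed[i0:i1] <- TRUE
      stream$valid[i0:i1] <- TRUE
      kind <- "blink"
    } else {
      stream$closed[i0:i1] <- TRUE
      stream$valid[i0:i1] <- FALSE
      kind <- "closure"
    }
    events[[length(events) + 1L]] <- data.frame(
      kind = kind, onset = onset, offset = offset, duration_ms = dur_ms,
      cx = NA_real_, cy = NA_real_
    )
  }

  ev <- if (length(events)) do.call(rbind, events) else ocular_event_frame()
  list(stream = stream, events = ev)
}

ocular_event_frame <- function() {
  data.frame(kind = character(0), onset = numeric(0), offset = numeric(0),
             duration_ms = numeric(0), cx = numeric(0), cy = numeric(0))
}

#' I-VT fixation/saccade classification
#'
#' Labels every usable gaze sample by angular velocity: below
#' `velocity_threshold` (default 30 deg/s) is fixation, at or above it is
#' saccade. Velocity uses the central difference of the Euclidean angular
#' displacement (forward/backward difference at the ends). Contiguous
#' same-class runs become events; runs are additionally split at closed or
#' invalid samples, so blinks split fixations. Fixations shorter than
#' `min_fix_dur` ms are relabelled saccade.
#'
#' @param stream a blink-repaired `gaze_stream` (see [repair_blinks()]).
#' @param velocity_threshold deg/s; boundary samples (exactly at the
#'   threshold) count as saccade.
#' @param min_fix_dur minimum fixation duration, ms.
#' @return Data frame of events (kind fixation/saccade, onset, offset,
#'   duration_ms, cx, cy; centroids for fixations only).
#' @export
ivt_classify <- function(stream, velocity_threshold = 30, min_fix_dur = 100) {
  fs <- gaze_fs(stream)
  dt <- 1 / fs
  usable <- stream$valid & !isTRUE_col(stream$closed)
  if (sum(usable) < 2) {
    warning("ivt_classify: fewer than 2 usable samples")
    return(ocular_event_frame())
  }
  n <- nrow(stream)
  x <- stream$x
  y <- stream$y
  t <- stream$t
  vel <- numeric(n)
  if (n >= 3) {
    i <- 2:(n - 1)
    vel[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
      (t[i + 1] - t[i - 1])
  }
  vel[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1])
  vel[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) /
    (t[n] - t[n - 1])

  # class: 1 fixation, 2 saccade, 0 unusable (splits runs)
  cls <- ifelse(vel < velocity_threshold, 1L, 2L)
  cls[!usable] <- 0L

  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(ocular_event_frame())
  i0 <- starts[keep]
  i1 <- ends[keep]
  dur_ms <- (i1 - i0 + 1L) * dt * 1000
  kind <- ifelse(r$values[keep] == 1L, "fixation", "saccade")
  kind[kind == "fixation" & dur_ms < min_fix_dur] <- "saccade"
  csx <- c(0, cumsum(x))
  csy <- c(0, cumsum(y))
  # mean of x[a..b] from the 0-prefixed cumulative sum
  seg_mean <- function(cs, a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
  cx <- ifelse(kind == "fixation", seg_mean(csx, i0, i1), NA_real_)
  cy <- ifelse(kind == "fixation", seg_mean(csy, i0, i1), NA_real_)
  data.frame(kind = kind, onset = t[i0], offset = t[i1] + dt,
             duration_ms = dur_ms, cx = cx, cy = cy)
}

isTRUE_col <- function(x) if (is.null(x)) FALSE else x

# keep only fixation rows if a kind column is present
filter_fixations <- function(fixations) {
  if ("kind" %in% names(fixations)) {
    fixations <- fixations[fixations$kind == "fixation", , drop = FALSE]
  }
  fixations
}

#' Parse a raw gaze stream into ocular events
#'
#' Convenience wrapper: blink repair followed by I-VT classification;
#' returns the repaired stream and the combined, time-ordered event list.
#'
#' @inheritParams ivt_classify
#' @inheritParams repair_blinks
#' @return List with `stream` and `events`.
#' @export
parse_ocular <- function(stream, velocity_threshold = 30, min_fix_dur = 100,
                         blink_bounds = c(75, 500)) {
  rep <- repair_blinks(stream, blink_bounds)
  if (isTRUE(attr(rep$stream, "unusable"))) {
    return(list(stream = rep$stream, events = rep$events))
  }
  ivt <- ivt_classify(rep$stream, velocity_threshold, min_fix_dur)
  ev <- rbind(rep$events, ivt)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  list(stream = rep$stream, events = ev)
}

#' Basic ocular features over a window
#'
#' Computes PERCLOS (fraction of window time with the eye proxy-closed,
#' i.e. zero-pupil time from blinks and long closures), blink frequency
#' (BF, blinks/min), mean blink duration (MBD, ms), mean fixation duration
#' (MFD, ms), fixation frequency (FF, fixations/min) and pupil diameter
#' variability (PDV, SD of pupil over valid open-eye samples).
#'
#' @param stream repaired `gaze_stream`.
#' @param events combined event table (see [parse_ocular()]).
#' @param window numeric length-2, half-open window `[t0, t1)` in s.
#' @return Named list with the six features and a `flags` character vector
#'   (e.g. "no_fixations").
#' @export
basic_ocular_features <- function(stream, events, window) {
  t0 <- window[1]
  t1 <- window[2]
  mins <- (t1 - t0) / 60
  in_win <- stream$t >= t0 & stream$t < t1
  ev <- events[events$onset >= t0 & events$onset < t1, , drop = FALSE]
  flags <- character(0)

  closed <- isTRUE_col(stream$closed)[in_win]
  perclos <- if (any(in_win)) mean(closed) else 0

  blinks <- ev[ev$kind == "blink", , drop = FALSE]
  bf <- nrow(blinks) / mins
  mbd <- if (nrow(blinks) > 0) mean(blinks$duration_ms) else 0

  fixs <- ev[ev$kind == "fixation", , drop = FALSE]
  ff <- nrow(fixs) / mins
  if (nrow(fixs) > 0) {
    mfd <- mean(fixs$duration_ms)
  } else {
    mfd <- 0
    flags <- c(flags, "no_fixations")
  }

  open_ok <- in_win & stream$valid & !isTRUE_col(stream$closed) &
    stream$pupil > 0
  pdv <- if (sum(open_ok) >= 2) stats::sd(stream$pupil[open_ok]) else 0

  list(PERCLOS = perclos, BF = bf, MBD = mbd, MFD = mfd, FF = ff,
       PDV = pdv, flags = flags)
}

#' Stationary gaze entropy
#'
#' Shannon entropy (bits) of the fixation-count distribution over the
#' non-empty AOI cells: `H = -sum p_i log2 p_i` with `p_i` the share of
#' fixations in cell i. Zero shares contribute zero. Bounded by
#' `log2(K)` for K non-empty cells.
#'
#' @param fixations data frame with fixation centroids `cx`, `cy`.
#' @param grid an [aoi_grid()].
#' @return Entropy in bits (0, with attribute `quality = "no_fixations"`,
#'   when no fixation is available).
#' @export
stationary_gaze_entropy <- function(fixations, grid) {
  fixations <- filter_fixations(fixations)
  if (nrow(fixations) == 0) {
    return(structure(0, quality = "no_fixations"))
  }
  cells <- aoi_cell(grid, fixations$cx, fixations$cy)
  p <- as.numeric(table(cells))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' AOI transition matrix of a fixation sequence
#'
#' Counts transitions between the AOI cells of consecutive fixations
#' (self-transitions included) and row-normalizes. The stationary weights
#' are the empirical shares of transition source cells.
#'
#' @inheritParams stationary_gaze_entropy
#' @return List with `P` (row-stochastic matrix over observed source
#'   cells), `pi` (stationary weights) and `cells` (cell labels).
#' @export
gaze_transition_matrix <- function(fixations, grid) {
  fixations <- filter_fixations(fixations)
  if (nrow(fixations) < 2) return(NULL)
  cells <- aoi_cell(grid, fixations$cx, fixations$cy)
  from <- cells[-length(cells)]
  to <- cells[-1]
  labs <- sort(unique(c(from, to)))
  Kn <- length(labs)
  cnt <- matrix(0, Kn, Kn, dimnames = list(labs, labs))
  for (i in seq_along(from)) {
    a <- as.character(from[i])
    b <- as.character(to[i])
    cnt[a, b] <- cnt[a, b] + 1
  }
  rs <- rowSums(cnt)
  P <- cnt
  nz <- rs > 0
  P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  pi_w <- rs / sum(rs)
  list(P = P, pi = pi_w, cells = labs)
}

#' Transition gaze entropy
#'
#' First-order Markov (conditional) entropy of the AOI transition process:
#' `H = -sum_i p_i sum_j p_ij log2 p_ij` with `p_ij` the row-normalized
#' transition probabilities and `p_i` the empirical source-cell shares.
#' Deterministic scanpaths (e.g. strict A-B alternation) give 0 bits; a
#' uniform chain over K cells gives `log2(K)`.
#'
#' @inheritParams stationary_gaze_entropy
#' @return Entropy in bits (0 with attribute `quality` when fewer than two
#'   fixations are available).
#' @export
transition_gaze_entropy <- function(fixations, grid) {
  tm <- gaze_transition_matrix(fixations, grid)
  if (is.null(tm)) {
    return(structure(0, quality = "too_few_fixations"))
  }
  row_ent <- apply(tm$P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(tm$pi * row_ent)
}

#' All eight ocular features for one window
#'
#' @param stream repaired `gaze_stream`.
#' @param events combined events (see [parse_ocular()]).
#' @param window half-open window `[t0, t1)` in s.
#' @param grid an [aoi_grid()].
#' @return Named list: PERCLOS, BF, MBD, MFD, FF, PDV, SGE, TGE, flags.
#' @export
ocular_features <- function(stream, events, window, grid) {
  basic <- basic_ocular_features(stream, events, window)
  fx <- events[events$kind == "fixation" & events$onset >= window[1] &
                 events$onset < window[2], , drop = FALSE]
  sge <- stationary_gaze_entropy(fx, grid)
  tge <- transition_gaze_entropy(fx, grid)
  flags <- unique(c(basic$flags, attr(sge, "quality"), attr(tge, "quality")))
  flags <- flags[!is.na(flags) & nzchar(flags)]
  c(basic[c("PERCLOS", "BF", "MBD", "MFD", "FF", "PDV")],
    list(SGE = as.numeric(sge), TGE = as.numeric(tge), flags = flags))
}
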