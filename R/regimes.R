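#' Physiological regime parameters
#'
#' A `regime_params` object bundles the generator-level description of one
#' vigilance state: tachogram structure (mean RR, LF/HF sinusoid amplitudes,
#' beat-to-beat noise), blink and eyelid-closure behaviour, fixation
#' dynamics, scanpath dispersion over the AOI grid, and pupil dynamics.
#'
#' @param mean_rr mean inter-beat interval, ms.
#' @param sdnn_target nominal total RR variability (SDNN), ms. Informational:
#'   the white-noise scale is derived from `rmssd_target`; `sdnn_target`
#'   records the preset's intended overall variability.
#' @param rmssd_target target beat-to-beat variability (RMSSD), ms; sets the
#'   white-noise SD of the tachogram (`sd = rmssd_target / sqrt(2)`).
#' @param lf_amp,hf_amp amplitudes (ms) of the 0.10 Hz and 0.25 Hz
#'   sinusoidal RR modulations (centres of the LF and HF bands).
#' @param blink_rate normal blinks per minute.
#' @param blink_dur_mean median blink duration, ms (kept within 75-500 ms).
#' @param closure_rate long eyelid closures (> 500 ms) per minute; these
#'   drive PERCLOS.
#' @param fix_dur_mean median fixation duration, ms.
#' @param aoi_concentration scalar in (0, 1] mixing the AOI transition chain
#'   toward the uniform chain: 1 gives uniform transitions (maximal scan
#'   entropy, broad scanning), small values concentrate transitions on the
#'   current cell and its neighbours (tunnelled scanning).
#' @param pupil_base mean pupil diameter, mm.
#' @param pupil_sd marginal SD of the AR(1) pupil process, mm.
#'
#' @return A `regime_params` list.
#' @export
regime_params <- function(mean_rr, sdnn_target, rmssd_target, lf_amp, hf_amp,
                          blink_rate, blink_dur_mean, closure_rate,
                          fix_dur_mean, aoi_concentration,
                          pupil_base, pupil_sd) {
  p <- list(
    mean_rr = mean_rr, sdnn_target = sdnn_target,
    rmssd_target = rmssd_target, lf_amp = lf_amp, hf_amp = hf_amp,
    blink_rate = blink_rate, blink_dur_mean = blink_dur_mean,
    closure_rate = closure_rate, fix_dur_mean = fix_dur_mean,
    aoi_concentration = aoi_concentration,
    pupil_base = pupil_base, pupil_sd = pupil_sd
  )
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("regime_params: all fields must be finite and non-negative")
  }
  if (aoi_concentration <= 0 || aoi_concentration > 1) {
    stop("regime_params: aoi_concentration must be in (0, 1]")
  }
  structure(p, class = "regime_params")
}

#' Alert and fatigue regime presets
#'
#' Default generator presets for the two vigilance states. They encode the
#' expected direction of fatigue-induced change: slower heart rate (higher
#' mean RR), higher beat-to-beat variability (RMSSD) with a lower LF/HF
#' balance (parasympathetic dominance), slower and more frequent blinks,
#' frequent long closures (higher PERCLOS), longer fixations (hence fewer
#' per minute), higher pupil variability, and a scanpath concentrated on
#' few AOIs (lower gaze entropy). Magnitudes are chosen for separability;
#' no quantitative effect sizes are published for this task.
#'
#' @return A `regime_params` object.
#' @export
alert_regime <- function() {
  regime_params(
    mean_rr = 750, sdnn_target = 35, rmssd_target = 25,
    lf_amp = 25, hf_amp = 10,
    blink_rate = 12, blink_dur_mean = 140, closure_rate = 0.1,
    fix_dur_mean = 250, aoi_concentration = 0.85,
    pupil_base = 3.6, pupil_sd = 0.15
  )
}

#' @rdname alert_regime
#' @export
fatigue_regime <- function() {
  regime_params(
    mean_rr = 850, sdnn_target = 55, rmssd_target = 45,
    lf_amp = 15, hf_amp = 30,
    blink_rate = 14, blink_dur_mean = 350, closure_rate = 8,
    fix_dur_mean = 300, aoi_concentration = 0.55,
    pupil_base = 3.3, pupil_sd = 0.22
  )
}

#' Interpolate between two regimes
#'
#' Linear field-wise interpolation; `w = 0` returns `a`, `w = 1` returns
#' `b`. Used to map the 7-point subjective fatigue score onto a continuum
#' between the alert and fatigue presets (`w = (sp7 - 1) / 6`).
#'
#' @param a,b `regime_params`.
#' @param w interpolation weight in \[0, 1\].
#' @return A `regime_params` object.
#' @export
regime_interpolate <- function(a, b, w) {
  stopifnot(inherits(a, "regime_params"), inherits(b, "regime_params"),
            w >= 0, w <= 1)
  fields <- names(unclass(a))
  vals <- lapply(fields, function(f) (1 - w) * a[[f]] + w * b[[f]])
  names(vals) <- fields
  do.call(regime_params, vals)
}

# Apply per-subject multiplicative baseline offsets. Cardiac/pupil/fixation
# baselines shift the features the cross-subject experiments rely on;
# blink-duration and closure-rate offsets encode the large inter-individual
# variability of spontaneous blinking, without which PERCLOS would be
# subject-invariant and no generalization gap could exist.
regime_apply_baseline <- function(params, mult) {
  for (f in names(mult)) params[[f]] <- params[[f]] * mult[[f]]
  params
}
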