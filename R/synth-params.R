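#' Circadian parameter set for the synthetic beat-train generator
#'
#' Describes the 24-h modulation of the three interval parameters (RR, PR
#' segment, QT) as one cosinor each — mesor \eqn{M}, amplitude \eqn{A} and
#' acrophase \eqn{\phi} of \eqn{M + A\cos(2\pi(t-\phi)/24)} — together with
#' the couplings that tie QT (and optionally the PR segment) to beat-to-beat
#' RR deviations, and the acute effect of locomotor activity on RR.
#'
#' Species presets reflect typical telemetry values: mouse RR mesor 100 ms
#' (HR ~600 bpm, sampled at 1 kHz), human RR mesor 900 ms. The PR-segment
#' acrophase is offset from the RR acrophase by +1.5 h by default, so the
#' phase-delay analyses have a known target.
#'
#' @param species `"mouse"` or `"human"`; selects the preset.
#' @param mesor_ms,amplitude_ms,acrophase_h named numeric vectors with
#'   entries `RR`, `PRseg`, `QT`; override the preset per parameter.
#' @param coupling_qt_rr slope (dimensionless) of QT on the beat's RR
#'   deviation from the RR mesor.
#' @param coupling_pr_rr same for the PR segment (default 0: the PR segment
#'   is buffered against acute RR change).
#' @param activity_gain_ms change in RR (ms) per unit of smoothed locomotor
#'   activity; negative values shorten RR during activity.
#' @param activity_tau_min time constant (min) of the exponential smoothing
#'   applied to activity counts before they act on RR.
#' @param noise_sd_ms named numeric vector of per-beat Gaussian noise SDs (ms).
#' @return An object of class `circadian_params`.
#' @export
circadian_params <- function(species = c("mouse", "human"),
                             mesor_ms = NULL, amplitude_ms = NULL,
                             acrophase_h = NULL,
                             coupling_qt_rr = 0.8, coupling_pr_rr = 0,
                             activity_gain_ms = NULL,
                             activity_tau_min = 15,
                             noise_sd_ms = NULL) {
  species <- match.arg(species)
  preset <- switch(species,
    mouse = list(
      mesor = c(RR = 100, PRseg = 15, QT = 40),
      amplitude = c(RR = 8, PRseg = 1.2, QT = 2),
      acrophase = c(RR = 6, PRseg = 7.5, QT = 6),
      gain = -0.5,
      noise = c(RR = 2, PRseg = 0.5, QT = 1)
    ),
    human = list(
      mesor = c(RR = 900, PRseg = 60, QT = 400),
      amplitude = c(RR = 70, PRseg = 5, QT = 10),
      acrophase = c(RR = 20, PRseg = 21.5, QT = 20),
      gain = -5,
      noise = c(RR = 15, PRseg = 2, QT = 5)
    )
  )
  merge_named <- function(base, override) {
    if (is.null(override)) return(base)
    stopifnot(!is.null(names(override)))
    base[names(override)] <- override
    base
  }
  mesor <- merge_named(preset$mesor, mesor_ms)
  amplitude <- merge_named(preset$amplitude, amplitude_ms)
  acrophase <- merge_named(preset$acrophase, acrophase_h)
  noise <- merge_named(preset$noise, noise_sd_ms)
  if (any(amplitude < 0)) abort("amplitudes must be >= 0")
  if (any(acrophase < 0 | acrophase >= 24)) abort("acrophases must lie in [0, 24)")
  structure(
    list(
      species = species,
      waves = tibble::tibble(
        parameter = c("RR", "PRseg", "QT"),
        mesor_ms = unname(mesor[c("RR", "PRseg", "QT")]),
        amplitude_ms = unname(amplitude[c("RR", "PRseg", "QT")]),
        acrophase_h = unname(acrophase[c("RR", "PRseg", "QT")])
      ),
      period_h = 24,
      coupling_qt_rr = coupling_qt_rr,
      coupling_pr_rr = coupling_pr_rr,
      activity_gain_ms = activity_gain_ms %||% preset$gain,
      activity_tau_min = activity_tau_min,
      noise_sd_ms = noise
    ),
    class = "circadian_params"
  )
}

#' @export
print.circadian_params <- function(x, ...) {
  cat("<circadian_params> species:", x$species, "\n")
  print(x$waves)
  cat("coupling QT~RR:", x$coupling_qt_rr,
      " PRseg~RR:", x$coupling_pr_rr,
      " activity gain:", x$activity_gain_ms, "ms/unit\n")
  invisible(x)
}

wave_par <- function(circ, parameter, field) {
  w <- circ$waves
  w[[field]][w$parameter == parameter]
}

#' Light/dark schedule and recording cadence
#'
#' Defines the lighting schedule (12:12 LD by default, time 0 = lights on of
#' day 1), the recording cadence (10-s telemetry sweeps every 5 min for mice,
#' or continuous recording for humans), and optional protocol features: a
#' phase shift of the LD cycle with gradual re-entrainment, a late-night
#' siesta window of reduced activity, and a sleep-deprivation day.
#'
#' @param days number of recording days.
#' @param species `"mouse"` or `"human"`.
#' @param lights_on,lights_off hours within the 24-h day (lights_on fixed at 0
#'   by the internal time base; lights_off sets photoperiod length).
#' @param phase_shift_day day (1-based) on which the LD cycle is shifted, or
#'   `NULL` for none.
#' @param shift_hours signed shift in hours; positive = advance. Must lie in
#'   (-12, 12].
#' @param reentrain_rate_h_per_day rate at which internal phase re-entrains
#'   after the shift (h/day).
#' @param siesta_window optional `c(start, end)` in ZT hours marking the
#'   late-night low-activity siesta, or `NULL`.
#' @param sleep_deprivation_day optional day kept awake (activity forced on),
#'   or `NULL`.
#' @param sweep_cadence_s interval between sweep starts (s); ignored when
#'   `continuous = TRUE`.
#' @param sweep_len_s sweep duration (s).
#' @param continuous if `TRUE` the ECG is recorded continuously (human
#'   laboratory style) rather than as cadenced telemetry sweeps.
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(days = 5, species = c("mouse", "human"),
                          lights_on = 0, lights_off = 12,
                          phase_shift_day = NULL, shift_hours = 0,
                          reentrain_rate_h_per_day = 1.5,
                          siesta_window = NULL,
                          sleep_deprivation_day = NULL,
                          sweep_cadence_s = 300, sweep_len_s = 10,
                          continuous = species == "human") {
  species <- match.arg(species)
  if (!is.null(phase_shift_day) &&
      (shift_hours <= -12 || shift_hours > 12)) {
    abort("shift_hours must lie in (-12, 12]")
  }
  if (!is.null(siesta_window) &&
      (length(siesta_window) != 2 || any(siesta_window < 0 | siesta_window > 24))) {
    abort("siesta_window must be c(start, end) within 0-24 h")
  }
  force(continuous)
  structure(
    list(
      days = days, species = species,
      lights_on = lights_on, lights_off = lights_off,
      phase_shift_day = phase_shift_day, shift_hours = shift_hours,
      reentrain_rate_h_per_day = reentrain_rate_h_per_day,
      siesta_window = siesta_window,
      sleep_deprivation_day = sleep_deprivation_day,
      sweep_cadence_s = sweep_cadence_s, sweep_len_s = sweep_len_s,
      continuous = continuous
    ),
    class = "schedule_spec"
  )
}

# Hours since recording start -> environmental zeitgeber time (ZT, hours
# after lights-on under the currently imposed LD cycle).
schedule_zt <- function(sched, t_h) {
  off <- rep(0, length(t_h))
  if (!is.null(sched$phase_shift_day)) {
    t_shift <- 24 * (sched$phase_shift_day - 1) - max(sched$shift_hours, 0)
    off[t_h >= t_shift] <- sched$shift_hours
  }
  (t_h + off - sched$lights_on) %% 24
}

# Internal circadian phase: re-entrains gradually after a phase shift.
schedule_internal_phase <- function(sched, t_h) {
  off <- rep(0, length(t_h))
  if (!is.null(sched$phase_shift_day)) {
    d_since <- t_h / 24 - (sched$phase_shift_day - 1)
    ramp <- pmax(d_since, 0) * sched$reentrain_rate_h_per_day * sign(sched$shift_hours)
    off <- if (sched$shift_hours >= 0) pmin(ramp, sched$shift_hours) else pmax(ramp, sched$shift_hours)
  }
  (t_h + off - sched$lights_on) %% 24
}

# TRUE when the environment is in its light phase at t_h (hours from start).
schedule_light <- function(sched, t_h) {
  zt <- schedule_zt(sched, t_h)
  zt >= 0 & zt < (sched$lights_off - sched$lights_on) %% 24
}

# Sweep start times (s) implied by the cadence.
schedule_sweep_starts <- function(sched) {
  total_s <- sched$days * 86400
  if (sched$continuous) return(0)
  seq(0, total_s - sched$sweep_len_s, by = sched$sweep_cadence_s)
}

#' ECG waveform morphology profile
#'
#' Each beat is rendered as a sum of Gaussian bumps grouped into three
#' complexes (P, QRS, T) whose anchors are moved beat-by-beat so that the
#' rule-defined fiducial landmarks reproduce the beat train's true intervals.
#' The bumps are deliberately smooth: every delineation rule used downstream
#' is defined through extrema and isoelectric crossings, which are well-posed
#' on this morphology. The mouse T wave is negative (its peak is a minimum),
#' the human T wave positive, and both P and T carry a small opposite-sign
#' companion bump so that the offset rules (return/crossing of the
#' isoelectric line, first deflection after the peak) have an exact,
#' noise-free answer.
#'
#' @param species `"mouse"` or `"human"`.
#' @return A tibble of class `morphology_profile` with columns `complex`,
#'   `wave`, `center_ms` (relative to the complex anchor), `sd_ms`, `amp_mv`,
#'   and attributes `species`, `white_noise_sd`, `baseline_wander_amp`,
#'   `default_fs`.
#' @export
morphology_profile <- function(species = c("mouse", "human")) {
  species <- match.arg(species)
  tab <- switch(species,
    mouse = tibble::tribble(
      ~complex, ~wave, ~center_ms, ~sd_ms, ~amp_mv,
      "P",   "P",    0,    3,    0.20,
      "P",   "Pn",   6,    1.5, -0.06,
      "QRS", "Q",   -6,    1.5, -0.20,
      "QRS", "R",    0,    2.5,  1.00,
      "QRS", "S",    5,    2,   -0.30,
      "T",   "T",    0,    6,   -0.25,
      "T",   "Tov", 12,    4,    0.06
    ),
    human = tibble::tribble(
      ~complex, ~wave, ~center_ms, ~sd_ms, ~amp_mv,
      "P",   "P",    0,   25,    0.10,
      "P",   "Pn",  55,   20,   -0.03,
      "QRS", "preQ", -40, 10,    0.04,
      "QRS", "Q",   -20,   7,   -0.08,
      "QRS", "R",    0,    9,    1.10,
      "QRS", "S",   28,   10,   -0.20,
      "T",   "T",    0,   50,    0.15,
      "T",   "Tu", 100,   35,   -0.08
    )
  )
  r_amp <- tab$amp_mv[tab$wave == "R"]
  stopifnot(abs(r_amp) > max(abs(tab$amp_mv[tab$wave != "R"])))
  structure(
    tab,
    species = species,
    white_noise_sd = if (species == "mouse") 0.02 else 0.01,
    baseline_wander_amp = 0.01,
    default_fs = if (species == "mouse") 1000 else 256,
    class = c("morphology_profile", class(tab))
  )
}
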