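# Shared fixtures, built once per test run and cached in-process.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# One hour of mouse telemetry (12 sweeps) with rendered waveform.
mouse_hour <- function() {
  cached_fixture("mouse_hour", {
    sched <- schedule_spec(days = 1 / 24, species = "mouse")
    circ <- circadian_params("mouse")
    tr <- synth_beat_train(circ, sched, seed = 101)
    rec <- synth_ecg_waveform(tr, morphology_profile("mouse"), fs = 1000,
                              seed = 102, noise_sd = 0.05)
    list(sched = sched, circ = circ, truth = tr, rec = rec)
  })
}

# The full study-scale fixture: 5 days of mouse telemetry at 1 kHz, noise SD
# 5% of the R amplitude, 4% artifact sweeps, siesta window, analyzed
# end-to-end. Built once; used by the fiducial-oracle and acceptance suites.
mouse_study <- function() {
  cached_fixture("mouse_study", {
    sched <- schedule_spec(days = 5, species = "mouse",
                           siesta_window = c(20, 22))
    act <- synth_behavior(sched, seed = 111)
    circ <- circadian_params("mouse")
    tr <- synth_beat_train(circ, sched, activity = act, seed = 112)
    rec <- synth_ecg_waveform(tr, morphology_profile("mouse"), fs = 1000,
                              seed = 113, noise_sd = 0.05,
                              artifact_rate = 0.04)
    res <- analyze_sweeps(rec)
    truth_med <- dplyr::summarise(
      dplyr::group_by(tr$beats, sweep_id),
      rr = median(rr_ms, na.rm = TRUE),
      pr = median(prseg_ms, na.rm = TRUE),
      qt = median(qt_ms, na.rm = TRUE), .groups = "drop"
    )
    list(sched = sched, act = act, circ = circ, truth = tr, rec = rec,
         res = res, truth_med = truth_med)
  })
}

# Render one sweep directly from bump positions (bypasses the generator) —
# used to build degenerate traces (e.g., beats without P waves).
render_sweep <- function(centers_ms, sds_ms, amps_mv, fs = 1000,
                         len_s = 10, noise_sd = 0, seed = 1) {
  set.seed(seed)
  t_ms <- (seq_len(len_s * fs) - 1) / fs * 1000
  chronoecg:::gaussian_bumps(t_ms, centers_ms, sds_ms, amps_mv) +
    rnorm(length(t_ms), 0, noise_sd)
}

# QRS-only beats whose tails vanish outside the +/-40 ms beat window, so the
# baseline region of a rendered sweep is exactly whatever is added to it.
qrs_bumps <- function(r_times_ms, amp = 1) {
  do.call(rbind, lapply(r_times_ms, function(r) {
    rbind(c(r - 6, 1.5, -0.2 * amp), c(r, 2.5, amp), c(r + 5, 2, -0.3 * amp))
  }))
}

# Mouse-like beat bumps (QRS + T with overshoot), optionally with P waves.
mouse_bumps <- function(r_times_ms, with_p = TRUE) {
  per_beat <- function(r) {
    waves <- rbind(
      c(r - 6, 1.5, -0.2), c(r, 2.5, 1.0), c(r + 5, 2, -0.3),
      c(r + 24, 6, -0.25), c(r + 36, 4, 0.06)
    )
    if (with_p) {
      waves <- rbind(waves, c(r - 27, 3, 0.2), c(r - 21, 1.5, -0.06))
    }
    waves
  }
  do.call(rbind, lapply(r_times_ms, per_beat))
}
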