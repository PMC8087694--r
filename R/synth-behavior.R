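#' Generate a synthetic locomotor-activity and body-temperature trace
#'
#' Activity is emitted as nonnegative Poisson counts per 5-min bin driven by
#' a species-appropriate rate profile: nocturnal for mice (high counts in the
#' dark phase), with an optional late-night siesta window of reduced rate.
#' After a phase shift of the LD cycle the profile follows the re-entraining
#' internal phase, so the activity acrophase moves toward the new schedule at
#' the configured rate. Body temperature is a sinusoid phase-locked to the
#' same internal phase plus measurement noise. A bin with count 0 is
#' "inactive" for all downstream rest/bout analyses.
#'
#' @param sched a [schedule_spec()].
#' @param seed integer seed; all randomness in this call derives from it.
#' @param rate_active,rate_rest Poisson rates (counts / 5 min) in the active
#'   and rest phases.
#' @param rate_siesta rate inside the siesta window.
#' @param temp_mean,temp_amp,temp_acrophase_h,temp_noise_sd body-temperature
#'   sinusoid parameters (degrees C, acrophase in internal ZT hours).
#' @return A tibble of class `activity_trace` with one row per 5-min bin:
#'   `t0_s`, `t_h`, `zt_h` (environmental), `psi_h` (internal phase),
#'   `light`, `activity`, `temp_c`.
#' @export
synth_behavior <- function(sched, seed,
                           rate_active = 6, rate_rest = 0.3,
                           rate_siesta = 0.2,
                           temp_mean = 36.2, temp_amp = 0.8,
                           temp_acrophase_h = 18, temp_noise_sd = 0.1) {
  set.seed(seed)
  t0 <- seq(0, sched$days * 86400 - 300, by = 300)
  t_h <- t0 / 3600
  psi <- schedule_internal_phase(sched, t_h)
  active_phase <- psi >= (sched$lights_off - sched$lights_on) %% 24
  if (sched$species == "human") active_phase <- !active_phase
  rate <- ifelse(active_phase, rate_active, rate_rest)
  if (!is.null(sched$siesta_window)) {
    in_siesta <- psi >= sched$siesta_window[1] & psi < sched$siesta_window[2]
    rate[in_siesta] <- rate_siesta
  }
  if (!is.null(sched$sleep_deprivation_day)) {
    day <- floor(t_h / 24) + 1
    rate[day == sched$sleep_deprivation_day] <- rate_active
  }
  activity <- rpois(length(rate), rate)
  temp <- temp_mean +
    temp_amp * cos(2 * pi * (psi - temp_acrophase_h) / 24) +
    rnorm(length(psi), 0, temp_noise_sd)
  out <- tibble::tibble(
    t0_s = t0, t_h = t_h,
    zt_h = schedule_zt(sched, t_h),
    psi_h = psi,
    light = schedule_light(sched, t_h),
    activity = activity, temp_c = temp
  )
  class(out) <- c("activity_trace", class(out))
  attr(out, "schedule") <- sched
  out
}

# Exponentially smoothed activity (the "effective" activity driving RR):
# first-order filter with time constant tau_min on the 5-min grid.
effective_activity <- function(activity, tau_min) {
  if (tau_min <= 0) return(as.numeric(activity))
  a <- exp(-5 / tau_min)
  as.numeric(stats::filter(as.numeric(activity), filter = a, method = "recursive"))
}
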