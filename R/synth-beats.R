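#' Generate a synthetic beat train with known interval ground truth
#'
#' Beat times accumulate from the instantaneous RR interval
#' \deqn{RR(t) = M_{RR} + A_{RR}\cos(2\pi(t-\phi_{RR})/24) +
#'   g\,\tilde a(t) + \epsilon,}
#' where \eqn{\tilde a(t)} is the exponentially smoothed activity count and
#' \eqn{g} the activity gain. QT follows its own cosinor plus
#' `coupling_qt_rr` times the beat's RR deviation from the RR mesor; the PR
#' segment follows an independent cosinor (acrophase typically offset from
#' RR's) plus `coupling_pr_rr` times the same deviation (0 by default). For
#' cadenced (telemetry) schedules beats are generated only within the 10-s
#' sweeps; for continuous schedules a single uninterrupted train is produced.
#'
#' Non-positive RR draws are resampled and counted; if more than 1% of draws
#' need resampling the call fails, since the requested noise level is then
#' incompatible with the mesor.
#'
#' @param circ a [circadian_params()].
#' @param sched a [schedule_spec()].
#' @param activity optional [synth_behavior()] output; when `NULL` the
#'   activity term is 0.
#' @param seed integer seed.
#' @return An object of class `ecg_truth`: a list with tibbles `beats`
#'   (per-beat times, true RR/PRseg/QT in ms, labels), `sweeps`, `episodes`
#'   (empty until [synth_arrhythmia_episode()] is used), the `activity`
#'   trace, and the generating `circ`/`sched`.
#' @export
synth_beat_train <- function(circ, sched, activity = NULL, seed) {
  stopifnot(inherits(circ, "circadian_params"), inherits(sched, "schedule_spec"))
  set.seed(seed)

  eff_fun <- function(t_s) rep(0, length(t_s))
  if (!is.null(activity)) {
    eff <- effective_activity(activity$activity, circ$activity_tau_min)
    eff_fun <- function(t_s) {
      idx <- pmin(pmax(floor(t_s / 300) + 1, 1), length(eff))
      eff[idx]
    }
  }

  m_rr <- wave_par(circ, "RR", "mesor_ms")
  a_rr <- wave_par(circ, "RR", "amplitude_ms")
  p_rr <- wave_par(circ, "RR", "acrophase_h")
  rr_mean_at <- function(t_s) {
    psi <- schedule_internal_phase(sched, t_s / 3600)
    cosine24(psi, m_rr, a_rr, p_rr) + circ$activity_gain_ms * eff_fun(t_s)
  }

  n_resampled <- 0L
  n_draws <- 0L
  draw_rr <- function(t_s) {
    mu <- rr_mean_at(t_s)
    rr <- rnorm(1, mu, circ$noise_sd_ms[["RR"]])
    n_draws <<- n_draws + 1L
    while (rr <= 0) {
      n_resampled <<- n_resampled + 1L
      n_draws <<- n_draws + 1L
      rr <- rnorm(1, mu, circ$noise_sd_ms[["RR"]])
      if (n_resampled > 0.01 * n_draws && n_draws > 100) {
        abort("more than 1% of RR draws were non-positive; check mesor/noise settings")
      }
    }
    rr
  }

  starts <- schedule_sweep_starts(sched)
  sweep_len <- if (sched$continuous) sched$days * 86400 else sched$sweep_len_s

  beats_per_sweep <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    t0 <- starts[k]
    t_end <- t0 + sweep_len
    # small random start offset so beats are not phase-locked to sweep starts
    t <- t0 + runif(1, 0, 0.5) * draw_rr(t0) / 1000
    times <- numeric(0)
    while (t < t_end) {
      times <- c(times, t)
      t <- t + draw_rr(t) / 1000
    }
    beats_per_sweep[[k]] <- times
  }

  n_beats <- vapply(beats_per_sweep, length, integer(1))
  times <- unlist(beats_per_sweep)
  sweep_id <- rep(seq_along(starts), n_beats)
  rr_ms <- unlist(lapply(beats_per_sweep, function(tt) {
    if (!length(tt)) return(numeric(0))
    c(NA_real_, diff(tt) * 1000)
  }))

  psi <- schedule_internal_phase(sched, times / 3600)
  rr_for_coupling <- rr_ms
  first_of_sweep <- is.na(rr_ms)
  rr_for_coupling[first_of_sweep] <- rr_mean_at(times[first_of_sweep])
  rr_dev <- rr_for_coupling - m_rr

  qt_ms <- cosine24(psi, wave_par(circ, "QT", "mesor_ms"),
                    wave_par(circ, "QT", "amplitude_ms"),
                    wave_par(circ, "QT", "acrophase_h")) +
    circ$coupling_qt_rr * rr_dev +
    rnorm(length(times), 0, circ$noise_sd_ms[["QT"]])
  prseg_ms <- cosine24(psi, wave_par(circ, "PRseg", "mesor_ms"),
                       wave_par(circ, "PRseg", "amplitude_ms"),
                       wave_par(circ, "PRseg", "acrophase_h")) +
    circ$coupling_pr_rr * rr_dev +
    rnorm(length(times), 0, circ$noise_sd_ms[["PRseg"]])
  if (any(qt_ms <= 0) || any(prseg_ms <= 0)) {
    abort("non-positive QT or PRseg generated; check mesor/noise settings")
  }

  sweeps <- tibble::tibble(
    sweep_id = seq_along(starts),
    t0_s = starts,
    t_h = starts / 3600,
    zt_h = schedule_zt(sched, starts / 3600),
    light = schedule_light(sched, starts / 3600),
    n_beats = n_beats
  )

  beats <- tibble::tibble(
    beat = seq_along(times),
    sweep_id = sweep_id,
    time_s = times,
    rr_ms = rr_ms,
    prseg_ms = prseg_ms,
    qt_ms = qt_ms,
    label = "normal",
    qrs_scale = 1,
    amp_factor = 1
  )

  structure(
    list(
      beats = beats, sweeps = sweeps,
      episodes = tibble::tibble(
        start_s = numeric(0), end_s = numeric(0),
        n_beats = integer(0), kind = character(0)
      ),
      activity = activity, circ = circ, sched = sched,
      n_resampled = n_resampled
    ),
    class = "ecg_truth"
  )
}

#' @export
print.ecg_truth <- function(x, ...) {
  cat("<ecg_truth>", nrow(x$beats), "beats in", nrow(x$sweeps), "sweeps over",
      x$sched$days, "days;", sum(x$beats$label != "normal"), "ectopic beats\n")
  invisible(x)
}

#' @exportS3Method
tidy.ecg_truth <- function(x, ...) x$beats

#' Inject a ventricular arrhythmia episode into a synthetic beat train
#'
#' Replaces a run of consecutive beats with labeled ventricular premature
#' complexes (VPCs). During the run the RR interval is compressed
#' (tachycardia), the QRS complex is widened by `qrs_scale`, and the R-wave
#' polarity is set per kind: monomorphic VT inverts every beat; bidirectional
#' VT (BVT) alternates beat-to-beat between an inverted full-amplitude QRS
#' and an upright low-amplitude QRS, so signed R amplitudes alternate in sign
#' across the run. Runs of at least 4 beats are annotated as episodes of the
#' requested kind; shorter runs leave labeled VPCs but no episode annotation.
#'
#' @param truth an `ecg_truth` from [synth_beat_train()].
#' @param kind `"VT"` or `"BVT"`.
#' @param run_length number of consecutive VPCs (>= 1).
#' @param at_beat global index of the first beat of the run; `NULL` picks a
#'   random beat (away from sweep edges) using `seed`.
#' @param seed integer seed (used only when `at_beat` is `NULL`).
#' @param rr_compression factor applied to RR during the run.
#' @param qrs_scale QRS widening factor.
#' @param alt_amp_factor signed amplitude factor of the alternating (upright)
#'   BVT beats, relative to the normal R amplitude.
#' @return The modified `ecg_truth`.
#' @export
synth_arrhythmia_episode <- function(truth, kind = c("VT", "BVT"),
                                     run_length, at_beat = NULL, seed = 1,
                                     rr_compression = 0.6, qrs_scale = 1.8,
                                     alt_amp_factor = 0.35) {
  kind <- match.arg(kind)
  stopifnot(run_length >= 1)
  beats <- truth$beats
  if (is.null(at_beat)) {
    set.seed(seed)
    # restrict to sweeps that can hold the whole run away from the edges
    ok <- beats$sweep_id %in% truth$sweeps$sweep_id[truth$sweeps$n_beats >
                                                      run_length + 6]
    pos <- which(ok & beats$label == "normal")
    pos <- pos[vapply(pos, function(i) {
      j <- i + run_length - 1
      if (j > nrow(beats)) return(FALSE)
      same <- which(beats$sweep_id == beats$sweep_id[i])
      # keep >= 3 normal beats on each side of the run within the sweep
      beats$sweep_id[j] == beats$sweep_id[i] &&
        i >= min(same) + 3 && j <= max(same) - 3
    }, logical(1))]
    if (!length(pos)) abort("no sweep can host an episode of this length")
    at_beat <- sample(pos, 1)
  }
  idx <- at_beat:(at_beat + run_length - 1)
  if (max(idx) > nrow(beats) || length(unique(beats$sweep_id[idx])) != 1) {
    abort("episode does not fit inside a single sweep")
  }
  sw <- beats$sweep_id[at_beat]
  sweep_rows <- which(beats$sweep_id == sw)

  # retime: compress RR during the run, keeping later beats contiguous
  rr <- beats$rr_ms[sweep_rows]
  local <- match(idx, sweep_rows)
  rr[local] <- rr[local] * rr_compression
  t <- beats$time_s[sweep_rows[1]] + c(0, cumsum(rr[-1] / 1000))
  beats$time_s[sweep_rows] <- t
  beats$rr_ms[sweep_rows] <- rr

  beats$label[idx] <- "VPC"
  beats$qrs_scale[idx] <- qrs_scale
  beats$amp_factor[idx] <- if (kind == "BVT") {
    ifelse(seq_len(run_length) %% 2 == 1, -1, alt_amp_factor)
  } else {
    -1
  }
  beats$prseg_ms[idx] <- NA_real_
  beats$qt_ms[idx] <- NA_real_
  truth$beats <- beats
  if (run_length >= 4) {
    truth$episodes <- dplyr::bind_rows(
      truth$episodes,
      tibble::tibble(
        start_s = beats$time_s[idx[1]], end_s = beats$time_s[idx[run_length]],
        n_beats = as.integer(run_length), kind = kind
      )
    )
  }
  truth
}
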