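# Waveform rendering: beats become sums of Gaussian bumps whose complexes are
# placed so that the rule-defined fiducial landmarks reproduce the beat
# train's true intervals exactly (to sample rounding).

# Landmark offsets internal to each complex, computed once per morphology on
# an oversampled noise-free rendering (0.05 ms grid). Offsets are relative to
# the complex anchor and, because complexes are separated by several bump
# SDs, independent of the beat-to-beat spacing.
canonical_landmarks <- function(morph) {
  species <- attr(morph, "species")
  dt <- 0.05
  render <- function(complex) {
    w <- morph[morph$complex == complex, ]
    lo <- min(w$center_ms - 6 * w$sd_ms)
    hi <- max(w$center_ms + 6 * w$sd_ms)
    t <- seq(lo, hi, by = dt)
    list(t = t, x = gaussian_bumps(t, w$center_ms, w$sd_ms, w$amp_mv))
  }

  qrs <- render("QRS")
  r_i <- which.max(qrs$x)
  if (species == "mouse") {
    q_i <- next_extremum(qrs$x, r_i, -1L, "min")
  } else {
    q_trough <- next_extremum(qrs$x, r_i, -1L, "min")
    q_i <- next_extremum(qrs$x, q_trough, -1L, "max")
  }
  d_q <- qrs$t[q_i]
  d_r <- qrs$t[r_i]

  p <- render("P")
  pk_i <- which.max(p$x)
  p_peak <- p$t[pk_i]
  if (species == "mouse") {
    po_i <- next_extremum(p$x, pk_i, 1L, "min")
    p_off <- p$t[po_i]
  } else {
    po <- next_crossing(p$x, pk_i, 0, 1L)
    p_off <- p$t[1] + (po - 1) * dt
  }

  tt <- render("T")
  if (species == "mouse") {
    tp_i <- which.min(tt$x)
    to <- next_crossing(tt$x, tp_i, 0, 1L)
    t_off <- tt$t[1] + (to - 1) * dt
  } else {
    tp_i <- which.max(tt$x)
    cr <- next_crossing(tt$x, tp_i, 0, 1L)
    to_i <- next_extremum(tt$x, ceiling(cr), 1L, "min")
    t_off <- tt$t[to_i]
  }
  t_peak <- tt$t[tp_i]

  list(q_on = d_q, r = d_r, p_peak = p_peak, p_off = p_off,
       t_peak = t_peak, t_off = t_off)
}

#' Render a synthetic beat train as a sampled ECG waveform
#'
#' Each beat becomes a sum of Gaussian bumps (see [morphology_profile()]).
#' Within every beat the QRS anchor is fixed to the true R time, the P
#' complex is shifted so that the P-offset landmark sits exactly `PRseg`
#' before the Q-onset landmark, and the T complex so that the T-offset
#' landmark sits exactly `QT` after Q onset; the emitted annotations are
#' therefore sample-accurate ground truth for the delineation rules.
#' Baseline wander and white noise are added last. Beats labeled `VPC` are
#' rendered without a P wave, with the QRS stretched by their `qrs_scale`
#' and scaled by their signed `amp_factor`, and with a reduced discordant T.
#'
#' A fraction `artifact_rate` of sweeps is corrupted with large baseline
#' wander, emulating movement artefact; these sweeps are expected to fail
#' downstream quality control.
#'
#' @param truth an `ecg_truth` from [synth_beat_train()].
#' @param morph a [morphology_profile()].
#' @param fs sampling rate in Hz (>= 500 for mouse, >= 128 for human).
#' @param seed integer seed for noise, wander phases and artifact placement.
#' @param noise_sd white noise SD in mV (default from the morphology).
#' @param baseline_wander_amp slow sinusoidal wander amplitude in mV.
#' @param wander_period_s wander period in seconds.
#' @param artifact_rate fraction of sweeps rendered with `artifact_amp`
#'   wander instead.
#' @param artifact_amp wander amplitude (mV) in artifact sweeps.
#' @return An object of class `ecg_recording`: sweep table with a list-column
#'   of sample vectors, plus per-beat `annotations` (1-based sample indices
#'   of P peak, P offset, Q onset, R, T peak, T offset; `NA` where a beat has
#'   no such landmark). Continuous schedules yield a single sweep row
#'   spanning the recording.
#' @export
synth_ecg_waveform <- function(truth, morph, fs = attr(morph, "default_fs"),
                               seed = 1, noise_sd = NULL,
                               baseline_wander_amp = NULL,
                               wander_period_s = 2,
                               artifact_rate = 0, artifact_amp = 0.5) {
  stopifnot(inherits(truth, "ecg_truth"), inherits(morph, "morphology_profile"))
  species <- attr(morph, "species")
  if (species == "mouse" && fs < 500) abort("mouse rendering requires fs >= 500 Hz")
  if (species == "human" && fs < 128) abort("human rendering requires fs >= 128 Hz")
  set.seed(seed)
  noise_sd <- noise_sd %||% attr(morph, "white_noise_sd")
  baseline_wander_amp <- baseline_wander_amp %||% attr(morph, "baseline_wander_amp")

  lm <- canonical_landmarks(morph)
  sched <- truth$sched
  sweep_len_s <- if (sched$continuous) sched$days * 86400 else sched$sweep_len_s
  n_samp <- round(sweep_len_s * fs)
  qt_ref <- wave_par(truth$circ, "QT", "mesor_ms")

  sweeps <- truth$sweeps
  artifact <- runif(nrow(sweeps)) < artifact_rate
  samples <- vector("list", nrow(sweeps))
  ann <- vector("list", nrow(sweeps))
  t_ms_grid <- (seq_len(n_samp) - 1) / fs * 1000

  waves_p <- morph[morph$complex == "P", ]
  waves_qrs <- morph[morph$complex == "QRS", ]
  waves_t <- morph[morph$complex == "T", ]

  for (k in seq_len(nrow(sweeps))) {
    b <- truth$beats[truth$beats$sweep_id == sweeps$sweep_id[k], ]
    r_ms <- (b$time_s - sweeps$t0_s[k]) * 1000
    normal <- b$label == "normal"
    q_on <- r_ms + lm$q_on - lm$r

    if (any(normal)) {
      rr_next <- c(diff(r_ms), Inf)
      # room needed after Q onset: this beat's QT, plus the next beat's P
      # complex and PR segment when the next beat carries a P wave
      next_p <- c(normal[-1], FALSE)
      need <- b$qt_ms + ifelse(next_p, c(b$prseg_ms[-1], 0), 0) +
        ifelse(next_p, 4 * max(morph$sd_ms), 2 * max(morph$sd_ms))
      too_short <- normal & rr_next < need
      if (any(too_short, na.rm = TRUE)) {
        abort(paste0("interval too short to fit morphology at beat ",
                     b$beat[which(too_short)[1]]))
      }
    }

    centers <- numeric(0); sds <- numeric(0); amps <- numeric(0)
    for (i in seq_len(nrow(b))) {
      if (normal[i]) {
        p_anchor <- q_on[i] - b$prseg_ms[i] - lm$p_off
        t_anchor <- q_on[i] + b$qt_ms[i] - lm$t_off
        centers <- c(centers, p_anchor + waves_p$center_ms,
                     r_ms[i] + waves_qrs$center_ms,
                     t_anchor + waves_t$center_ms)
        sds <- c(sds, waves_p$sd_ms, waves_qrs$sd_ms, waves_t$sd_ms)
        amps <- c(amps, waves_p$amp_mv, waves_qrs$amp_mv, waves_t$amp_mv)
      } else {
        sc <- b$qrs_scale[i]
        af <- b$amp_factor[i]
        t_anchor <- q_on[i] + qt_ref - lm$t_off
        centers <- c(centers, r_ms[i] + waves_qrs$center_ms * sc,
                     t_anchor + waves_t$center_ms)
        sds <- c(sds, waves_qrs$sd_ms * sc, waves_t$sd_ms)
        amps <- c(amps, waves_qrs$amp_mv * af,
                  waves_t$amp_mv * (-sign(af)) * 0.5)
      }
    }
    x <- gaussian_bumps(t_ms_grid, centers, sds, amps)
    w_amp <- if (artifact[k]) artifact_amp else baseline_wander_amp
    x <- x + w_amp * sin(2 * pi * t_ms_grid / (wander_period_s * 1000) +
                           runif(1, 0, 2 * pi))
    x <- x + rnorm(n_samp, 0, noise_sd)
    samples[[k]] <- x

    to_sample <- function(ms) {
      s <- round(ms / 1000 * fs) + 1L
      s[s < 1L | s > n_samp] <- NA_integer_
      s
    }
    ann[[k]] <- tibble::tibble(
      beat = b$beat, sweep_id = b$sweep_id, time_s = b$time_s,
      label = b$label,
      r_sample = to_sample(r_ms),
      p_peak_sample = ifelse(normal,
        to_sample(q_on - b$prseg_ms - lm$p_off + lm$p_peak), NA_integer_),
      p_off_sample = ifelse(normal, to_sample(q_on - b$prseg_ms), NA_integer_),
      q_on_sample = to_sample(q_on),
      t_peak_sample = ifelse(normal,
        to_sample(q_on + b$qt_ms - lm$t_off + lm$t_peak), NA_integer_),
      t_off_sample = ifelse(normal, to_sample(q_on + b$qt_ms), NA_integer_)
    )
  }

  rec_sweeps <- dplyr::mutate(sweeps, fs = fs, species = species,
                              artifact = artifact)
  rec_sweeps$samples <- samples
  structure(
    list(
      sweeps = rec_sweeps,
      annotations = dplyr::bind_rows(ann),
      truth = truth, fs = fs, species = species,
      landmarks = lm
    ),
    class = "ecg_recording"
  )
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat("<ecg_recording>", nrow(x$sweeps), "sweeps @", x$fs, "Hz (",
      x$species, "),", nrow(x$annotations), "annotated beats\n")
  invisible(x)
}

#' Extract one sweep's sample vector from a recording
#' @param rec an `ecg_recording`.
#' @param sweep_id sweep identifier.
#' @return Numeric vector of samples (mV).
#' @export
sweep_samples <- function(rec, sweep_id) {
  i <- match(sweep_id, rec$sweeps$sweep_id)
  if (is.na(i)) abort("unknown sweep_id")
  rec$sweeps$samples[[i]]
}
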