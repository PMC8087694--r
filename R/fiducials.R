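# Species-dialect PQRST delineation, per-beat intervals, per-sweep medians.
#
# Operationalization shared by both dialects: a "deflection" is a local
# extremum of the lightly smoothed trace (an upward/"positive" deflection is
# a local minimum, a downward/"negative" one a local maximum); a "crossing"
# of the isoelectric line is the first sample at/beyond the level, linearly
# interpolated between the bracketing samples.

#' Estimate the isoelectric level ahead of one beat
#'
#' Median of the baseline segment between the previous beat's T offset (or
#' the window start) and a guard gap before the expected P wave.
#'
#' @param x sweep samples (mV).
#' @param seg_start,seg_end segment bounds (samples).
#' @return List with `level` (mV), `noise` (MAD-based SD estimate of the
#'   segment) and `valid` (`FALSE` when the segment is shorter than 5
#'   samples, in which case the whole-sweep median is returned).
#' @export
estimate_isoelectric <- function(x, seg_start, seg_end) {
  seg_start <- max(1L, round(seg_start))
  seg_end <- min(length(x), round(seg_end))
  if (is.na(seg_start) || is.na(seg_end) || seg_end - seg_start + 1 < 5) {
    return(list(level = median(x), noise = mad(x), valid = FALSE))
  }
  seg <- x[seg_start:seg_end]
  list(level = median(seg), noise = mad(seg), valid = TRUE)
}

# per-species search guards (ms)
fiducial_guards <- function(species) {
  if (species == "mouse") {
    list(p_hi = 10, p_lo_frac = 0.5, t_lo = 10, t_hi_frac = 0.6,
         q_limit = 40, iso_guard = 38)
  } else {
    list(p_hi = 60, p_lo_frac = 0.6, t_lo = 60, t_hi_frac = 0.65,
         q_limit = 150, iso_guard = 260)
  }
}

#' Delineate every filtered beat of a sweep
#'
#' Applies the species dialect. Mouse: P offset is the first upward
#' deflection right of the P peak; Q onset the first upward deflection left
#' of the R peak; the T peak is the minimum between the R wave and the next
#' P wave, and T offset the return to the isoelectric line after it.
#' Human: P offset is the crossing of the isoelectric line right of the P
#' peak; Q onset is the first downward deflection left of the Q trough; the
#' T peak is the maximum between the R wave and the next P wave, and T
#' offset the first upward deflection after the trace crosses the
#' isoelectric line. First/last beats receive only the landmarks their
#' windows allow; landmark-ordering violations invalidate only the affected
#' landmarks.
#'
#' @param x sweep samples (mV).
#' @param beats a [template_filter()] result (only included beats are
#'   delineated).
#' @param fs sampling rate (Hz).
#' @param species `"mouse"` or `"human"`.
#' @param smooth_width width (samples) of the centred moving average applied
#'   before deflection detection of narrow (QRS-scale) landmarks.
#' @param smooth_width_broad wider moving average used for the broad P/T
#'   landmarks; defaults to `smooth_width` for mouse (all mouse waves are
#'   narrow at 1 kHz) and 9 samples for human recordings, whose T waves are
#'   an order of magnitude wider than the sampling interval.
#' @return A tibble with one row per delineated beat: sample indices
#'   `r_peak`, `p_peak`, `p_off`, `q_on`, `t_peak`, `t_off` (fractional for
#'   interpolated crossings), `iso` level, and per-landmark validity flags.
#' @export
annotate_sweep <- function(x, beats, fs, species = c("mouse", "human"),
                           smooth_width = 3, smooth_width_broad = NULL) {
  species <- match.arg(species)
  g <- fiducial_guards(species)
  sm <- moving_average(x, smooth_width)
  smooth_width_broad <- smooth_width_broad %||%
    (if (species == "mouse") smooth_width else 9)
  smb <- if (smooth_width_broad == smooth_width) sm else
    moving_average(x, smooth_width_broad)
  r_idx <- beats$candidates[beats$included]
  nb <- length(r_idx)
  if (!nb) {
    return(tibble::tibble(
      r_peak = integer(0), p_peak = integer(0), p_off = numeric(0),
      q_on = integer(0), t_peak = integer(0), t_off = numeric(0),
      iso = numeric(0), p_valid = logical(0), q_valid = logical(0),
      t_valid = logical(0)
    ))
  }
  ms <- function(v) round(v / 1000 * fs)
  med_rr <- if (nb > 1) median(diff(r_idx)) else ms(600)

  P_peak <- Q_on <- rep(NA_integer_, nb)
  P_off <- T_off <- rep(NA_real_, nb)
  T_peak <- rep(NA_integer_, nb)
  Iso <- rep(NA_real_, nb)
  P_valid <- Q_valid <- T_valid <- rep(FALSE, nb)
  prev_t_off <- NA_real_
  for (i in seq_len(nb)) {
    r <- r_idx[i]
    r_prev <- if (i > 1) r_idx[i - 1] else NA_integer_
    r_next <- if (i < nb) r_idx[i + 1] else NA_integer_
    rr_prev <- if (!is.na(r_prev)) r - r_prev else med_rr
    rr_next <- if (!is.na(r_next)) r_next - r else med_rr

    # isoelectric level from the pre-P baseline
    seg_start <- if (!is.na(prev_t_off)) prev_t_off + ms(5) else
      if (!is.na(r_prev)) r_prev + 0.55 * rr_prev else 1
    iso_est <- estimate_isoelectric(x, seg_start, r - ms(g$iso_guard))
    iso <- iso_est$level
    noise <- max(iso_est$noise, 1e-6)

    # ---- P wave -----------------------------------------------------------
    p_lo <- if (!is.na(r_prev)) round(r_prev + g$p_lo_frac * rr_prev) else
      max(1L, r - round(0.45 * med_rr))
    p_hi <- r - ms(g$p_hi)
    p_peak <- NA_integer_; p_off <- NA_real_; p_valid <- FALSE
    if (p_hi - p_lo >= 3) {
      win <- p_lo:p_hi
      p_peak <- win[which.max(smb[win])]
      prominent <- (smb[p_peak] - iso) > 4 * noise
      if (prominent) {
        p_off <- if (species == "mouse") {
          as.numeric(next_extremum(sm, p_peak, 1L, "min", limit = r))
        } else {
          next_crossing(sm, p_peak, iso, 1L, limit = r)
        }
        p_valid <- !is.na(p_off) && p_off > p_peak
      }
    }

    # ---- Q onset ----------------------------------------------------------
    q_limit <- max(1L, r - ms(g$q_limit))
    q_on <- if (species == "mouse") {
      next_extremum(sm, r, -1L, "min", limit = q_limit)
    } else {
      q_trough <- next_extremum(sm, r, -1L, "min", limit = q_limit)
      if (!is.na(q_trough)) {
        next_extremum(sm, q_trough, -1L, "max", limit = q_limit)
      } else NA_integer_
    }
    q_valid <- !is.na(q_on) && q_on < r
    if (q_valid && p_valid && p_off > q_on) {
      # ordering violation: drop the P side only
      p_valid <- FALSE
    }

    # ---- T wave -----------------------------------------------------------
    t_lo <- r + ms(g$t_lo)
    t_hi <- min(length(x), round(r + g$t_hi_frac * rr_next))
    t_peak <- NA_integer_; t_off <- NA_real_; t_valid <- FALSE
    if (t_hi - t_lo >= 3) {
      win <- t_lo:t_hi
      t_peak <- if (species == "mouse") win[which.min(smb[win])] else
        win[which.max(smb[win])]
      t_limit <- min(length(x), round(r + 0.95 * rr_next))
      if (species == "mouse") {
        t_off <- next_crossing(smb, t_peak, iso, 1L, limit = t_limit)
      } else {
        cr <- next_crossing(smb, t_peak, iso, 1L, limit = t_limit)
        if (!is.na(cr)) {
          t_off <- as.numeric(next_extremum(smb, ceiling(cr), 1L, "min",
                                            limit = t_limit))
        }
      }
      t_valid <- !is.na(t_off) && !is.na(t_peak) && t_off >= t_peak
    }

    prev_t_off <- if (t_valid) t_off else NA_real_
    P_peak[i] <- p_peak; P_off[i] <- p_off; Q_on[i] <- q_on
    T_peak[i] <- t_peak; T_off[i] <- t_off; Iso[i] <- iso
    P_valid[i] <- p_valid; Q_valid[i] <- q_valid; T_valid[i] <- t_valid
  }
  tibble::tibble(
    r_peak = r_idx, p_peak = P_peak, p_off = P_off, q_on = Q_on,
    t_peak = T_peak, t_off = T_off, iso = Iso,
    p_valid = P_valid, q_valid = Q_valid, t_valid = T_valid
  )
}

#' Per-beat intervals from fiducial landmarks
#'
#' RR is the spacing between successive R peaks (assigned to the later
#' beat); the PR segment runs from P offset to Q onset; QT from Q onset to
#' T offset. Intervals whose landmarks are invalid are `NA`.
#'
#' @param fids an [annotate_sweep()] tibble.
#' @param fs sampling rate (Hz).
#' @return `fids` with `rr_ms`, `prseg_ms`, `qt_ms` columns appended.
#' @export
compute_intervals <- function(fids, fs) {
  to_ms <- function(d) d / fs * 1000
  n <- nrow(fids)
  rr <- c(NA_real_, diff(fids$r_peak)) |> to_ms()
  prseg <- ifelse(fids$p_valid & fids$q_valid,
                  to_ms(fids$q_on - fids$p_off), NA_real_)
  qt <- ifelse(fids$q_valid & fids$t_valid,
               to_ms(fids$t_off - fids$q_on), NA_real_)
  dplyr::mutate(fids, rr_ms = rr, prseg_ms = prseg, qt_ms = qt)
}

#' Reduce one sweep to its median parameters
#'
#' Medians are taken over the valid beats of the sweep; HR is derived from
#' the median RR (60000 / RR ms). Sweeps failing quality control, or with no
#' valid beats, are flagged excluded and carry `NA` parameters downstream.
#'
#' @param intervals a [compute_intervals()] tibble.
#' @param qc a [sweep_qc()] row.
#' @return One-row tibble: `rr_ms`, `prseg_ms`, `qt_ms`, `hr_bpm`,
#'   `n_valid_beats`, `qc_pass`, `excluded`.
#' @export
summarize_sweep <- function(intervals, qc) {
  med <- function(v) if (any(!is.na(v))) median(v, na.rm = TRUE) else NA_real_
  rr <- med(intervals$rr_ms)
  out <- tibble::tibble(
    rr_ms = rr,
    prseg_ms = med(intervals$prseg_ms),
    qt_ms = med(intervals$qt_ms),
    hr_bpm = ifelse(is.na(rr), NA_real_, 60000 / rr),
    n_valid_beats = nrow(intervals),
    qc_pass = qc$pass,
    excluded = !qc$pass || nrow(intervals) == 0
  )
  out
}
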