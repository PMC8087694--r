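# Rule-based ventricular premature complex (VPC) labeling, VT/bidirectional
# VT episode calling, and time-of-day incidence testing.

# QRS width at `frac` of the beat's own R amplitude: the contiguous run of
# samples around r where |x - iso| exceeds frac * |x[r] - iso|, in ms.
qrs_width_ms <- function(x, r, iso, fs, frac = 0.25, max_ms = 60) {
  n <- length(x)
  amp <- abs(x[r] - iso)
  if (amp == 0) return(NA_real_)
  thr <- frac * amp
  lim <- round(max_ms / 1000 * fs)
  lo <- r
  while (lo > 1 && lo > r - lim && abs(x[lo - 1] - iso) > thr) lo <- lo - 1
  hi <- r
  while (hi < n && hi < r + lim && abs(x[hi + 1] - iso) > thr) hi <- hi + 1
  (hi - lo) / fs * 1000
}

#' Label beats as normal or ventricular premature complexes
#'
#' A beat is a VPC when its QRS is widened relative to the sweep's mean-beat
#' template (width ratio above `width_factor`) and its QRS axis deviates
#' from the template's: the signed R amplitude, as a fraction of the
#' template's signed R amplitude, falls below `polarity_ratio_max`. A sign
#' flip (inverted QRS) gives a negative ratio and always satisfies the
#' second clause; a widened but non-inverted beat of normal amplitude does
#' not. A prematurity flag (preceding RR below `premature_factor` times the
#' local median RR) is recorded but not required for the morphology call.
#'
#' @param x sweep samples (mV).
#' @param beats a [template_filter()] result (all candidates are labeled).
#' @param fs sampling rate (Hz).
#' @param width_factor QRS widening threshold (default 1.5).
#' @param polarity_ratio_max axis-deviation threshold on the signed
#'   amplitude ratio (default 0.5).
#' @param premature_factor prematurity threshold on the preceding RR.
#' @return A tibble of class `beat_labels`: `r_peak`, `label`
#'   (`normal`/`VPC`/`unlabeled`), `qrs_width_ms`, `signed_r_mv`,
#'   `width_ratio`, `amp_ratio`, `premature`.
#' @export
classify_beats <- function(x, beats, fs, width_factor = 1.5,
                           polarity_ratio_max = 0.5,
                           premature_factor = 0.8) {
  stopifnot(inherits(beats, "beat_set"))
  r_idx <- beats$candidates
  if (is.null(beats$template)) {
    abort("template unavailable (fewer than 2 candidates); cannot classify")
  }
  # morphology is measured on the lightly smoothed trace so the width run
  # and signed amplitude are not cut short by single noisy samples
  sm <- moving_average(x, 3L)
  iso <- median(sm)
  tpl <- moving_average(beats$template, 3L)
  tpl_r <- beats$half_w + 1L
  tpl_iso <- median(tpl)
  tpl_width <- qrs_width_ms(tpl, tpl_r, tpl_iso, fs)
  tpl_amp <- tpl[tpl_r] - tpl_iso

  width <- vapply(r_idx, function(r) qrs_width_ms(sm, r, iso, fs), numeric(1))
  signed <- sm[r_idx] - iso
  width_ratio <- width / tpl_width
  amp_ratio <- signed / tpl_amp
  rr_prev <- c(NA_real_, diff(r_idx)) / fs * 1000
  med_rr <- median(diff(r_idx)) / fs * 1000
  label <- ifelse(
    is.na(width), "unlabeled",
    ifelse(width_ratio > width_factor & amp_ratio < polarity_ratio_max,
           "VPC", "normal")
  )
  out <- tibble::tibble(
    r_peak = r_idx, label = label, qrs_width_ms = width,
    signed_r_mv = signed, width_ratio = width_ratio, amp_ratio = amp_ratio,
    premature = !is.na(rr_prev) & rr_prev < premature_factor * med_rr
  )
  class(out) <- c("beat_labels", class(out))
  out
}

#' Call ventricular tachycardia episodes from beat labels
#'
#' Maximal runs of at least four consecutive VPCs become VT episodes; a run
#' whose signed R amplitudes additionally alternate in sign beat-to-beat is
#' bidirectional VT (BVT). Runs of three or fewer VPCs are never called.
#'
#' @param labels a [classify_beats()] tibble (or any tibble with `label`,
#'   `signed_r_mv`, `r_peak`).
#' @param fs sampling rate (Hz); when given, episode durations in seconds
#'   are included.
#' @return Tibble of episodes: `start_beat`, `end_beat` (row indices),
#'   `length`, `kind`, and optional `duration_s`.
#' @export
call_episodes <- function(labels, fs = NULL) {
  r <- rle(labels$label == "VPC")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 4)
  out <- lapply(runs, function(i) {
    s <- starts[i]; e <- ends[i]
    amps <- labels$signed_r_mv[s:e]
    alternating <- all(sign(amps[-1]) != sign(amps[-length(amps)]))
    tibble::tibble(
      start_beat = s, end_beat = e, length = e - s + 1L,
      kind = if (alternating) "BVT" else "VT",
      duration_s = if (!is.null(fs)) {
        (labels$r_peak[e] - labels$r_peak[s]) / fs
      } else NA_real_
    )
  })
  if (!length(out)) {
    return(tibble::tibble(start_beat = integer(0), end_beat = integer(0),
                          length = integer(0), kind = character(0),
                          duration_s = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Detect arrhythmia episodes across a whole recording
#'
#' Runs detection, template building, beat classification and episode
#' calling on every sweep.
#'
#' @param rec an `ecg_recording` (or sweep tibble as for
#'   [analyze_sweeps()]).
#' @param ... passed to [classify_beats()].
#' @return Tibble of called episodes with `sweep_id` and onset time.
#' @export
detect_arrhythmias <- function(rec, ...) {
  sweeps <- if (inherits(rec, "ecg_recording")) rec$sweeps else rec
  out <- lapply(seq_len(nrow(sweeps)), function(k) {
    x <- sweeps$samples[[k]]
    fs <- sweeps$fs[k]
    species <- sweeps$species[k]
    cand <- detect_r_peaks(x, fs, species)
    if (length(cand) < 2) return(NULL)
    beats <- template_filter(x, as.integer(cand), fs, species)
    labels <- classify_beats(x, beats, fs, ...)
    ep <- call_episodes(labels, fs)
    if (!nrow(ep)) return(NULL)
    ep$sweep_id <- sweeps$sweep_id[k]
    ep$start_s <- sweeps$t0_s[k] + labels$r_peak[ep$start_beat] / fs
    ep
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble::tibble(start_beat = integer(0), end_beat = integer(0),
                          length = integer(0), kind = character(0),
                          duration_s = numeric(0), sweep_id = integer(0),
                          start_s = numeric(0))
  }
  out
}

#' Pearson chi-square test on a 2x2 incidence table
#'
#' No continuity correction (df = 1), matching the incidence comparisons of
#' time-of-day arrhythmia susceptibility; the odds ratio is reported
#' alongside.
#'
#' @param table 2x2 matrix of nonnegative counts (condition x outcome).
#' @return Tibble: `statistic`, `df`, `p_value`, `odds_ratio`.
#' @export
incidence_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::tibble(
    statistic = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, odds_ratio = or
  )
}

#' Susceptibility across repeated trials
#'
#' A subject is susceptible when an episode of the requested kind was
#' called on every trial.
#'
#' @param ... logical vectors (one per trial) of per-subject episode calls.
#' @return Logical vector.
#' @export
susceptible <- function(...) {
  Reduce(`&`, list(...))
}
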