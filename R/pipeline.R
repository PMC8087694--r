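# End-to-end sweep analysis: detection -> template filter -> QC ->
# delineation -> per-sweep medians (+ geometric HRV).

#' Analyze every sweep of a recording
#'
#' Runs the full per-sweep chain: R-peak detection by amplitude
#' thresholding, template-matching beat filtering, the three quality-control
#' rules, species-dialect fiducial delineation, per-beat intervals, sweep
#' medians and the geometric HRV measure.
#'
#' @param sweeps a sweep table: an `ecg_recording` (from
#'   [synth_ecg_waveform()]), a `telemetry_recording` (from
#'   [read_telemetry_csv()]), or a tibble as returned by [segment_sweeps()]
#'   with columns `sweep_id`, `t0_s`, `fs`, `species`, `samples`.
#' @param window optional fixed [amplitude_window()]; default derives one
#'   per sweep via [auto_amplitude_window()].
#' @param theta template mismatch threshold.
#' @param refractory_ms override of the species refractory.
#' @param keep_beats if `TRUE`, the per-beat annotation table is attached as
#'   attribute `beats`.
#' @return A tibble with one row per sweep: `sweep_id`, `t0_s`, `t_h`,
#'   `rr_ms`, `prseg_ms`, `qt_ms`, `hr_bpm`, `hrv`, `n_valid_beats`,
#'   `qc_pass`, `rule_failures`, QC metrics, `excluded`.
#' @export
analyze_sweeps <- function(sweeps, window = NULL, theta = 0.2,
                           refractory_ms = NULL, keep_beats = FALSE) {
  if (inherits(sweeps, "ecg_recording")) sweeps <- sweeps$sweeps
  if (inherits(sweeps, "telemetry_recording")) sweeps <- sweeps$sweeps
  stopifnot(all(c("sweep_id", "t0_s", "fs", "species", "samples") %in%
                  names(sweeps)))
  n <- nrow(sweeps)
  rows <- vector("list", n)
  beat_rows <- if (keep_beats) vector("list", n) else NULL
  for (k in seq_len(n)) {
    x <- sweeps$samples[[k]]
    fs <- sweeps$fs[k]
    species <- sweeps$species[k]
    cand <- detect_r_peaks(x, fs, species, window = window,
                           refractory_ms = refractory_ms)
    win <- attr(cand, "window") %||% window
    beats <- template_filter(x, as.integer(cand), fs, species, theta = theta)
    qc <- sweep_qc(x, beats, win)
    fids <- annotate_sweep(x, beats, fs, species)
    ints <- compute_intervals(fids, fs)
    summ <- summarize_sweep(ints, qc)
    hrv <- geometric_hrv(ints$rr_ms)
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(sweep_id = sweeps$sweep_id[k], t0_s = sweeps$t0_s[k],
                     t_h = sweeps$t0_s[k] / 3600),
      summ["rr_ms"], summ["prseg_ms"], summ["qt_ms"], summ["hr_bpm"],
      tibble::tibble(hrv = hrv$measure),
      summ[c("n_valid_beats", "qc_pass", "excluded")],
      qc[c("rule_failures", "mean_beat_amp", "baseline_variation",
           "rejection_fraction")]
    )
    if (keep_beats) {
      beat_rows[[k]] <- dplyr::mutate(ints, sweep_id = sweeps$sweep_id[k],
                                      .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_beats) attr(out, "beats") <- dplyr::bind_rows(beat_rows)
  out
}
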