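# R-wave detection, template-matching beat filtering, and the three
# sweep-level quality-control rules.

#' Amplitude window for R-wave detection
#'
#' @param lower,upper bounds in mV, `0 < lower < upper`.
#' @return An object of class `amplitude_window`.
#' @export
amplitude_window <- function(lower, upper) {
  if (!(lower > 0 && upper > lower)) abort("need 0 < lower < upper")
  structure(list(lower = lower, upper = upper), class = "amplitude_window")
}

#' Default amplitude window from the sweep itself
#'
#' The window is an operator setting; absent an explicit choice it is set
#' relative to the typical R-peak scale, estimated as the median of the
#' per-second maxima of the absolute baseline-centred signal (every second
#' contains at least one R wave for any physiological heart rate). The
#' bounds are `[0.25, 2]` times that scale: low enough that clean beats
#' clear the 3-times-lower QC rule, high enough to reject P/T waves.
#' Quantile-of-signal rules are not used because the R wave's duty cycle
#' differs by an order of magnitude between species.
#'
#' @param x sweep samples (mV).
#' @param fs sampling rate (Hz), used for the 1-s blocks.
#' @return An [amplitude_window()].
#' @export
auto_amplitude_window <- function(x, fs = length(x)) {
  y <- abs(x - median(x))
  n_block <- max(1L, floor(length(y) / fs))
  block_max <- vapply(seq_len(n_block), function(b) {
    max(y[((b - 1) * fs + 1):min(b * fs, length(y))])
  }, numeric(1))
  scale <- median(block_max)
  if (scale <= 0) scale <- max(y, .Machine$double.eps)
  amplitude_window(0.25 * scale, 2 * scale)
}

species_refractory_ms <- function(species) {
  if (species == "mouse") 50 else 250
}

species_template_halfwidth_ms <- function(species) {
  if (species == "mouse") 40 else 350
}

#' Detect candidate R waves by amplitude thresholding
#'
#' Local maxima of the absolute baseline-centred signal whose amplitude lies
#' inside the window, thinned so accepted peaks are at least one refractory
#' period apart (larger peaks win; ties go to the earlier sample). Detection
#' runs on the rectified signal so inverted (ectopic) complexes are still
#' found; the signed amplitude is recoverable from the samples.
#'
#' @param x sweep samples (mV).
#' @param fs sampling rate (Hz).
#' @param species `"mouse"` or `"human"` (sets the default refractory).
#' @param window an [amplitude_window()] or `NULL` for
#'   [auto_amplitude_window()].
#' @param refractory_ms minimum peak separation (ms); default 50 (mouse) or
#'   250 (human).
#' @return Sorted integer sample indices of candidate R peaks, with the
#'   window used attached as attribute `window`.
#' @export
detect_r_peaks <- function(x, fs, species = c("mouse", "human"),
                           window = NULL, refractory_ms = NULL) {
  species <- match.arg(species)
  refractory_ms <- refractory_ms %||% species_refractory_ms(species)
  if (refractory_ms <= 0) abort("refractory must be positive")
  window <- window %||% auto_amplitude_window(x, fs)
  y <- abs(x - median(x))
  n <- length(y)
  if (n < 3) return(integer(0))
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
               FALSE)
  cand <- which(is_peak & y >= window$lower & y <= window$upper)
  if (!length(cand)) {
    return(structure(integer(0), window = window))
  }
  refr <- refractory_ms / 1000 * fs
  ord <- cand[order(-y[cand], cand)]
  keep <- logical(length(cand))
  names(keep) <- cand
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= refr)) {
      accepted <- c(accepted, i)
    }
  }
  structure(sort(accepted), window = window)
}

#' Filter detected beats by template matching
#'
#' The template is the mean beat waveform of the sweep: the average of the
#' fixed windows (odd length, centred on R) around every candidate whose
#' window fits inside the sweep. Each beat's mismatch is `1 - r` with `r`
#' its Pearson correlation with the template; beats with mismatch above
#' `theta` are excluded. Beats whose window is truncated by the sweep edge
#' are excluded and counted as rejected.
#'
#' @param x sweep samples (mV).
#' @param candidates candidate R indices from [detect_r_peaks()].
#' @param fs sampling rate (Hz).
#' @param species `"mouse"` or `"human"` (sets the default window).
#' @param theta mismatch threshold (default 0.2).
#' @param halfwidth_ms half-width of the beat window (ms).
#' @return An object of class `beat_set`: list with `candidates`, logical
#'   `included`, `mismatch`, the `template` vector, `half_w` (samples),
#'   `rejection_fraction`, and `flagged` (TRUE when fewer than two
#'   candidates made filtering impossible and all were retained).
#' @export
template_filter <- function(x, candidates, fs, species = c("mouse", "human"),
                            theta = 0.2, halfwidth_ms = NULL) {
  species <- match.arg(species)
  halfwidth_ms <- halfwidth_ms %||% species_template_halfwidth_ms(species)
  half_w <- max(1L, round(halfwidth_ms / 1000 * fs))
  n <- length(x)
  k <- length(candidates)
  if (k < 2) {
    return(structure(
      list(candidates = candidates, included = rep(TRUE, k),
           mismatch = rep(0, k), template = NULL, half_w = half_w,
           rejection_fraction = 0, flagged = TRUE),
      class = "beat_set"
    ))
  }
  full <- candidates - half_w >= 1 & candidates + half_w <= n
  win_mat <- vapply(candidates[full],
                    function(r) x[(r - half_w):(r + half_w)],
                    numeric(2 * half_w + 1))
  template <- rowMeans(win_mat)
  mismatch <- rep(NA_real_, k)
  mismatch[full] <- 1 - suppressWarnings(
    as.numeric(cor(win_mat, template))
  )
  mismatch[full][is.na(mismatch[full])] <- 1   # zero-variance window
  included <- !is.na(mismatch) & mismatch <= theta
  structure(
    list(candidates = candidates, included = included, mismatch = mismatch,
         template = template, half_w = half_w,
         rejection_fraction = sum(!included) / k, flagged = FALSE),
    class = "beat_set"
  )
}

#' Sweep-level quality control
#'
#' A sweep fails when any of three rules trips:
#' `low_amplitude` - the mean amplitude of the discriminated beat waveforms
#' is below 3 times the lower limit of the amplitude window;
#' `baseline_noise` - the baseline variation (1.4826 x the median absolute
#' deviation of the samples outside the beat windows) exceeds 1/3 of that
#' lower limit; `high_rejection` - more than 20% of detected events were
#' excluded by template matching. A sweep with no beats fails
#' `low_amplitude`.
#'
#' @param x sweep samples (mV).
#' @param beats a [template_filter()] result.
#' @param window the [amplitude_window()] used for detection.
#' @return A one-row tibble: `pass`, `rule_failures` (comma-separated),
#'   `mean_beat_amp`, `baseline_variation`, `rejection_fraction`.
#' @export
sweep_qc <- function(x, beats, window) {
  stopifnot(inherits(beats, "beat_set"))
  n <- length(x)
  in_beat <- rep(FALSE, n)
  for (r in beats$candidates) {
    lo <- max(1, r - beats$half_w); hi <- min(n, r + beats$half_w)
    in_beat[lo:hi] <- TRUE
  }
  baseline <- x[!in_beat]
  base_med <- if (length(baseline)) median(baseline) else median(x)
  baseline_var <- if (length(baseline) >= 5) mad(baseline) else NA_real_

  incl <- beats$candidates[beats$included]
  mean_amp <- if (length(incl)) mean(abs(x[incl] - base_med)) else NA_real_

  fails <- character(0)
  if (!length(incl) || is.na(mean_amp) || mean_amp < 3 * window$lower) {
    fails <- c(fails, "low_amplitude")
  }
  if (!is.na(baseline_var) && baseline_var > window$lower / 3) {
    fails <- c(fails, "baseline_noise")
  }
  if (beats$rejection_fraction > 0.2) {
    fails <- c(fails, "high_rejection")
  }
  tibble::tibble(
    pass = length(fails) == 0,
    rule_failures = paste(fails, collapse = ","),
    mean_beat_amp = mean_amp,
    baseline_variation = baseline_var,
    rejection_fraction = beats$rejection_fraction
  )
}
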