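# Acute locomotor-activity effects on ECG parameters, separated from the
# circadian profile via an at-rest 24-h constrained sine normalization.
#
# Conventions: the activity trace is counts per 5-min bin; a bin is
# "inactive" iff its count is 0; a "bout" is a maximal run of nonzero bins.

align_param_activity <- function(param, activity) {
  if (is.null(activity)) {
    abort("no activity trace available; activity analyses refuse to run")
  }
  idx <- match(round(param$t_h * 12), round(activity$t_h * 12))
  if (anyNA(idx)) abort("parameter sweeps do not align to the 5-min activity grid")
  idx
}

#' Circadian profile of a parameter at rest
#'
#' Fits a 24-h constrained sine (cosinor) to the data points at which the
#' animal had not been active in the preceding `lookback_min` minutes
#' (strictly zero counts in every 5-min bin of the lookback, including the
#' point's own bin).
#'
#' @param param tibble with `t_h` (hours) and `value` (one row per sweep).
#' @param activity an `activity_trace` on the matching 5-min grid.
#' @param lookback_min inactivity lookback (minutes).
#' @return An object of class `rest_fit`: the [cosinor_fit()] on rest
#'   points, the logical `rest` mask, `n_rest`, `resid_sd`.
#' @export
at_rest_profile <- function(param, activity, lookback_min = 30) {
  idx <- align_param_activity(param, activity)
  nb <- ceiling(lookback_min / 5)
  act <- activity$activity
  rest_bin <- vapply(seq_along(act), function(i) {
    lo <- i - nb
    if (lo < 1) return(FALSE)
    all(act[lo:i] == 0)
  }, logical(1))
  rest <- rest_bin[idx] & is.finite(param$value)
  if (sum(rest) < 8) abort("insufficient rest coverage: fewer than 8 rest points")
  ph <- sort(unique(param$t_h[rest] %% 24))
  gaps <- diff(c(ph, ph[1] + 24))
  if ((24 - max(gaps)) <= 12) {
    abort(sprintf("rest points span only %.1f h of circadian phase (gap %.1f h)",
                  24 - max(gaps), max(gaps)))
  }
  fit <- cosinor_fit(param$t_h[rest], param$value[rest])
  structure(
    list(fit = fit, rest = rest, n_rest = sum(rest),
         resid_sd = sqrt(fit$resid_var), lookback_min = lookback_min),
    class = "rest_fit"
  )
}

#' @export
print.rest_fit <- function(x, ...) {
  cat("<rest_fit>", x$n_rest, "rest points (lookback", x$lookback_min,
      "min); ")
  print(x$fit)
  invisible(x)
}

# evaluate the rest fit at arbitrary clock times
predict_rest <- function(rest_fit, t_h) {
  f <- rest_fit$fit
  cosine24(t_h %% f$period, f$mesor, f$amplitude, f$acrophase_h, f$period)
}

#' Parameter response aligned to the cessation of activity
#'
#' Isolates activity bouts followed by at least `run_min` minutes of
#' complete inactivity, aligns the parameter to the cessation (time 0), and
#' expresses values as deviations from the at-rest circadian fit at the
#' matching clock phase, so the circadian component is removed and only the
#' acute activity effect remains.
#'
#' @param param tibble with `t_h`, `value`.
#' @param activity an `activity_trace`.
#' @param rest_fit an [at_rest_profile()] result.
#' @param run_min required inactivity run after the bout (minutes).
#' @return An object of class `aligned_response`: tibble `curve`
#'   (`rel_min`, `mean`, `sem`, `n`), `n_events`, `anchor`.
#' @export
inactivity_aligned_response <- function(param, activity, rest_fit,
                                        run_min = 45) {
  idx <- align_param_activity(param, activity)
  act <- activity$activity
  nb <- ceiling(run_min / 5)
  # cessation = first zero bin after a nonzero bin, with >= nb zero bins ahead
  zero_run <- rle(act == 0)
  ends <- cumsum(zero_run$lengths)
  starts <- ends - zero_run$lengths + 1
  events <- starts[zero_run$values & zero_run$lengths >= nb & starts > 1]
  dev <- param$value - predict_rest(rest_fit, param$t_h)
  rel <- seq(0, run_min, by = 5)
  rows <- lapply(events, function(e) {
    bins <- e + seq_along(rel) - 1
    keep <- bins <= length(act)
    pos <- match(bins[keep], idx)
    tibble::tibble(rel_min = rel[keep], dev = dev[pos])
  })
  curve <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$rel_min),
    mean = mean(.data$dev, na.rm = TRUE),
    sem = sd(.data$dev, na.rm = TRUE) / sqrt(sum(!is.na(.data$dev))),
    n = sum(!is.na(.data$dev)), .groups = "drop"
  )
  structure(list(curve = curve, n_events = length(events),
                 event_bins = events, anchor = "activity_cessation"),
            class = "aligned_response")
}

#' Parameter response around transient activity bouts
#'
#' A transient bout is a single-run of activity preceded by more than
#' `pre_min` and followed by more than `post_min` minutes of inactivity.
#' Values are expressed relative to the mean of the preceding `pre_min`
#' rest bin(s); events whose windows would overlap an earlier event are
#' dropped and counted.
#'
#' @param param tibble with `t_h`, `value`.
#' @param activity an `activity_trace`.
#' @param pre_min,post_min required inactivity before/after (minutes).
#' @return An `aligned_response` anchored at bout onset (`rel_min` 0), with
#'   `n_dropped` overlapping events.
#' @export
transient_bout_response <- function(param, activity, pre_min = 5,
                                    post_min = 20) {
  idx <- align_param_activity(param, activity)
  act <- activity$activity
  npre <- ceiling(pre_min / 5); npost <- ceiling(post_min / 5)
  r <- rle(act != 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bouts <- which(r$values)
  events <- integer(0); bout_len <- integer(0)
  for (bi in bouts) {
    s <- starts[bi]; e <- ends[bi]
    if (s - npre < 1 || e + npost > length(act)) next
    if (!all(act[(s - npre):(s - 1)] == 0)) next
    if (!all(act[(e + 1):(e + npost)] == 0)) next
    events <- c(events, s); bout_len <- c(bout_len, e - s + 1)
  }
  n_dropped <- 0L
  if (length(events) > 1) {
    keep <- rep(TRUE, length(events))
    last_end <- -Inf
    for (i in seq_along(events)) {
      lo <- events[i] - npre
      hi <- events[i] + bout_len[i] - 1 + npost
      if (lo <= last_end) { keep[i] <- FALSE; n_dropped <- n_dropped + 1L }
      else last_end <- hi
    }
    events <- events[keep]; bout_len <- bout_len[keep]
  }
  rel <- seq(-pre_min, post_min, by = 5)
  rows <- lapply(seq_along(events), function(i) {
    bins <- events[i] + rel / 5
    keep <- bins >= 1 & bins <= length(act)
    pos <- match(bins[keep], idx)
    base <- mean(param$value[match(events[i] - seq_len(npre), idx)],
                 na.rm = TRUE)
    tibble::tibble(rel_min = rel[keep], dev = param$value[pos] - base)
  })
  if (!length(rows)) {
    curve <- tibble::tibble(rel_min = rel, mean = NA_real_, sem = NA_real_,
                            n = 0L)
  } else {
    curve <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(rows), .data$rel_min),
      mean = mean(.data$dev, na.rm = TRUE),
      sem = sd(.data$dev, na.rm = TRUE) / sqrt(sum(!is.na(.data$dev))),
      n = sum(!is.na(.data$dev)), .groups = "drop"
    )
  }
  structure(list(curve = curve, n_events = length(events),
                 n_dropped = n_dropped, anchor = "bout_onset"),
            class = "aligned_response")
}

#' @export
print.aligned_response <- function(x, ...) {
  cat("<aligned_response>", x$n_events, "events, anchor:", x$anchor, "\n")
  print(x$curve, n = 5)
  invisible(x)
}

#' Siesta versus preceding-activity contrast
#'
#' Mean parameter value inside the (late-night) siesta window versus the
#' window of equal length immediately preceding it, per day, yielding one
#' paired contrast per animal. When no window is supplied it is located as
#' the 2-h window minimizing mean activity within ZT 18-24.
#'
#' @param param tibble with `t_h`, `value`.
#' @param activity an `activity_trace`.
#' @param siesta_window `c(start, end)` in ZT hours, or `NULL` to locate it.
#' @param comparison_window optional explicit comparison window (must have
#'   the same length as the siesta window); default: the window immediately
#'   preceding the siesta.
#' @return Tibble: `siesta_mean`, `before_mean`, `contrast`
#'   (siesta - before), `n_days`, window bounds.
#' @export
siesta_contrast <- function(param, activity, siesta_window = NULL,
                            comparison_window = NULL) {
  if (is.null(siesta_window)) {
    starts <- seq(18, 22, by = 0.25)
    zt <- activity$zt_h
    act_mean <- vapply(starts, function(s) {
      mean(activity$activity[zt >= s & zt < s + 2])
    }, numeric(1))
    s <- starts[which.min(act_mean)]
    siesta_window <- c(s, s + 2)
  }
  len <- siesta_window[2] - siesta_window[1]
  if (len <= 0) abort("siesta window must have positive length")
  before <- comparison_window %||% c(siesta_window[1] - len, siesta_window[1])
  if (abs(diff(before) - len) > 1e-9) {
    abort("comparison window must match the siesta window length")
  }
  zt <- param$t_h %% 24
  max_h <- max(param$t_h)
  if (siesta_window[2] > 24 + 1e-9 || before[1] < 0 || max_h < 24) {
    abort("siesta/comparison windows must lie inside the recorded days")
  }
  in_s <- zt >= siesta_window[1] & zt < siesta_window[2]
  in_b <- zt >= before[1] & zt < before[2]
  s_mean <- mean(param$value[in_s], na.rm = TRUE)
  b_mean <- mean(param$value[in_b], na.rm = TRUE)
  tibble::tibble(
    siesta_mean = s_mean,
    before_mean = b_mean,
    contrast = s_mean - b_mean,
    n_days = length(unique(floor(param$t_h[in_s] / 24))),
    window_start_zt = siesta_window[1], window_end_zt = siesta_window[2]
  )
}
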