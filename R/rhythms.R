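# Per-subject normalization and binning, cosinor rhythmometry, circular
# acrophase statistics, cross-correlogram phase delays, delta-RR dependency
# curves, profile smoothing, moving-average detrending, RR heatmaps.

#' Z-score a parameter across the full session
#'
#' Centres and scales by the mean and SD of the included sweeps only
#' (sample SD, n-1 denominator); excluded sweeps do not influence the
#' normalization.
#'
#' @param values numeric vector (one entry per sweep).
#' @param include logical mask of sweeps entering the normalization
#'   (default: all finite values).
#' @return Numeric vector of z-scores (`NA` where excluded/missing).
#' @export
zscore_session <- function(values, include = NULL) {
  include <- include %||% rep(TRUE, length(values))
  use <- include & is.finite(values)
  if (sum(use) < 2) abort("need at least 2 included finite values")
  s <- sd(values[use])
  if (s == 0) abort("zero variance: cannot z-score")
  out <- (values - mean(values[use])) / s
  out[!is.finite(values)] <- NA_real_
  out
}

#' Bin a sweep-level series onto a regular time grid
#'
#' Bin means on a fixed-width grid over the whole session, with coverage
#' bookkeeping: a subject whose fraction of nonempty bins falls below
#' `coverage_min` is flagged for exclusion from waveform (profile) analyses.
#'
#' @param time_h sweep times (hours from session start).
#' @param values sweep values (z-units or ms).
#' @param width_min bin width in minutes (must divide 24 h).
#' @param coverage_min minimum fraction of nonempty bins.
#' @param span_h total session span in hours (default: ceiling of the data).
#' @return A tibble of class `binned_series` with `bin_center_h`, `value`,
#'   `n`; attributes `coverage`, `excluded`, `width_min`.
#' @export
bin_series <- function(time_h, values, width_min = 5, coverage_min = 0.7,
                       span_h = NULL) {
  if ((24 * 60) %% width_min != 0) abort("width_min must divide 24 h")
  w_h <- width_min / 60
  span_h <- span_h %||% (ceiling(max(time_h, na.rm = TRUE) / w_h) * w_h)
  edges <- seq(0, span_h, by = w_h)
  centers <- edges[-length(edges)] + w_h / 2
  idx <- findInterval(time_h, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(centers)] <- NA
  ok <- !is.na(idx) & is.finite(values)
  sums <- tapply(values[ok], factor(idx[ok], levels = seq_along(centers)),
                 mean)
  n <- tapply(rep(1, sum(ok)), factor(idx[ok], levels = seq_along(centers)),
              sum)
  n[is.na(n)] <- 0
  out <- tibble::tibble(
    bin_center_h = centers,
    value = as.numeric(sums),
    n = as.integer(n)
  )
  coverage <- mean(out$n > 0)
  attr(out, "coverage") <- coverage
  attr(out, "excluded") <- coverage < coverage_min
  attr(out, "width_min") <- width_min
  class(out) <- c("binned_series", class(out))
  out
}

#' Cosinor fit with a fixed period
#'
#' Least-squares fit of \eqn{M + A\cos(2\pi(t-\phi)/P)} via the linear
#' harmonic regression \eqn{y = M + b_1\cos(\omega t) + b_2\sin(\omega t)};
#' amplitude \eqn{A = \sqrt{b_1^2+b_2^2}}, acrophase
#' \eqn{\phi = \mathrm{atan2}(b_2, b_1)/\omega} modulo the period. The
#' rhythmicity p-value is the F-test of the two harmonic regressors against
#' the intercept-only model (a zero-amplitude test); a permutation variant
#' is available.
#'
#' @param time_h observation times (hours; may span several days).
#' @param values observed values.
#' @param period period in hours (default 24).
#' @param p_method `"ftest"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @return An object of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_h`, `p_value`, `resid_var`, `n`, and the underlying `lm`.
#' @export
cosinor_fit <- function(time_h, values, period = 24,
                        p_method = c("ftest", "permutation"),
                        n_perm = 1000) {
  p_method <- match.arg(p_method)
  if (inherits(time_h, "binned_series")) {
    values <- time_h$value
    time_h <- time_h$bin_center_h
  }
  ok <- is.finite(time_h) & is.finite(values)
  time_h <- time_h[ok]; values <- values[ok]
  if (length(values) < 8) abort("need at least 8 observations")
  phase_span <- diff(range(time_h %% period))
  if (phase_span <= period / 2 && length(unique(round(time_h %/% period))) == 1) {
    abort("observations must span more than half the period")
  }
  w <- 2 * pi / period
  cc <- cos(w * time_h); ss <- sin(w * time_h)
  fit <- lm(values ~ cc + ss)
  b <- coef(fit)
  if (anyNA(b)) abort("degenerate design: collinear harmonic regressors")
  amplitude <- sqrt(b[["cc"]]^2 + b[["ss"]]^2)
  acrophase <- (atan2(b[["ss"]], b[["cc"]]) / w) %% period
  f0 <- lm(values ~ 1)
  p <- anova(f0, fit)[2, "Pr(>F)"]
  if (p_method == "permutation") {
    obs <- amplitude
    perm <- replicate(n_perm, {
      yb <- sample(values)
      bb <- coef(lm(yb ~ cc + ss))
      sqrt(bb[["cc"]]^2 + bb[["ss"]]^2)
    })
    p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  }
  structure(
    list(mesor = unname(b[1]), amplitude = amplitude,
         acrophase_h = acrophase, p_value = p,
         resid_var = sum(fit$residuals^2) / fit$df.residual,
         n = length(values), period = period, fit = fit),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat("<cosinor_fit> mesor", format(x$mesor, digits = 4),
      "amplitude", format(x$amplitude, digits = 4),
      "acrophase", format(x$acrophase_h, digits = 4), "h, p =",
      format.pval(x$p_value), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "acrophase_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h)
  )
}

#' @exportS3Method
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, resid_var = x$resid_var, n = x$n,
                 period = x$period)
}

#' Watson-Williams test on per-subject acrophases
#'
#' Circular one-way comparison of group mean acrophases. Hours are mapped to
#' angles (24 h = 2 pi); the F statistic uses the standard concentration
#' correction \eqn{K = 1 + 3/(8\hat\kappa)}. The result is flagged
#' unreliable when the pooled mean resultant length falls below 0.45, where
#' the test's assumptions break down.
#'
#' @param acrophase_h numeric vector of acrophases (hours, 0-24).
#' @param group grouping factor (>= 2 subjects per group).
#' @param period hours per cycle.
#' @return An object of class `watson_williams`: `statistic`, `df1`, `df2`,
#'   `p_value`, `group_means_h`, `r_w`, `reliable`.
#' @export
acrophase_stats <- function(acrophase_h, group, period = 24) {
  group <- factor(group)
  if (any(table(group) < 2)) abort("need >= 2 subjects per group")
  k <- nlevels(group)
  n <- length(acrophase_h)
  ang <- acrophase_h * 2 * pi / period
  Rg <- tapply(seq_len(n), group, function(i) {
    length(i) * resultant_length(acrophase_h[i], period)
  })
  R <- n * resultant_length(acrophase_h, period)
  r_w <- sum(Rg) / n
  kappa <- a1inv(r_w)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((n - k) * (sum(Rg) - R)) / ((k - 1) * (n - sum(Rg)))
  p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  means <- tapply(acrophase_h, group, circular_mean_h, period = period)
  structure(
    list(statistic = unname(Fstat), df1 = k - 1, df2 = n - k,
         p_value = unname(p), group_means_h = means, r_w = r_w,
         reliable = r_w >= 0.45),
    class = "watson_williams"
  )
}

#' @export
print.watson_williams <- function(x, ...) {
  cat("<watson_williams> F(", x$df1, ",", x$df2, ") =",
      format(x$statistic, digits = 4), ", p =", format.pval(x$p_value),
      if (!x$reliable) " [unreliable: low concentration]", "\n")
  invisible(x)
}

#' @exportS3Method
tidy.watson_williams <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, r_w = x$r_w, reliable = x$reliable)
}

#' Cross-correlogram phase delay between two binned series
#'
#' Pearson correlation over pairwise-complete bins at every lag within
#' `max_lag_h`, followed by a Gaussian fit (height, mean, SD) to the
#' contiguous positive-correlation region around the correlogram's argmax;
#' the fitted mean is the phase delay of `b` relative to `a` (positive =
#' `b` lags `a`). If the nonlinear fit fails the argmax lag is returned,
#' flagged `method = "argmax"`.
#'
#' @param a,b `binned_series` (or tibbles with `bin_center_h`, `value`) on
#'   the same grid.
#' @param max_lag_h maximum lag scanned (hours).
#' @param min_overlap minimum fraction of bins that must overlap at lag 0.
#' @return An object of class `phase_delay`: `delay_h`, `sd_h`, `height`,
#'   `method`, and the `correlogram` tibble.
#' @export
crosscorr_phase <- function(a, b, max_lag_h = 12, min_overlap = 0.7) {
  va <- a$value; vb <- b$value
  if (length(va) != length(vb)) abort("series must share the bin grid")
  step_h <- diff(a$bin_center_h[1:2])
  ok0 <- sum(is.finite(va) & is.finite(vb)) / length(va)
  if (ok0 < min_overlap) abort("insufficient overlapping coverage")
  max_k <- floor(max_lag_h / step_h)
  lags <- (-max_k):max_k
  r <- vapply(lags, function(k) {
    if (k >= 0) {
      xa <- va[seq_len(length(va) - k)]
      xb <- vb[seq_len(length(vb) - k) + k]
    } else {
      xa <- va[seq_len(length(va) + k) - k]
      xb <- vb[seq_len(length(vb) + k)]
    }
    use <- is.finite(xa) & is.finite(xb)
    if (sum(use) < 8) return(NA_real_)
    suppressWarnings(cor(xa[use], xb[use]))
  }, numeric(1))
  cg <- tibble::tibble(lag_h = lags * step_h, r = r)

  i_max <- which.max(r)
  if (!length(i_max) || is.na(r[i_max]) || r[i_max] <= 0) {
    abort("correlogram has no positive peak")
  }
  # contiguous positive region around the peak
  lo <- i_max; while (lo > 1 && !is.na(r[lo - 1]) && r[lo - 1] > 0) lo <- lo - 1
  hi <- i_max; while (hi < length(r) && !is.na(r[hi + 1]) && r[hi + 1] > 0) hi <- hi + 1
  seg <- cg[lo:hi, ]
  seg <- seg[is.finite(seg$r), ]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r ~ h * exp(-(lag_h - mu)^2 / (2 * s^2)), data = seg,
      start = list(h = max(seg$r), mu = cg$lag_h[i_max],
                   s = max(2 * step_h, diff(range(seg$lag_h)) / 4)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(delay_h = cg$lag_h[i_max], sd_h = NA_real_,
                height = r[i_max], method = "argmax", correlogram = cg)
  } else {
    cf <- coef(fit)
    out <- list(delay_h = unname(cf["mu"]), sd_h = abs(unname(cf["s"])),
                height = unname(cf["h"]), method = "gaussian",
                correlogram = cg)
  }
  structure(out, class = "phase_delay")
}

#' @export
print.phase_delay <- function(x, ...) {
  cat("<phase_delay>", format(x$delay_h, digits = 3), "h (",
      x$method, "fit, peak r =", format(x$height, digits = 3), ")\n")
  invisible(x)
}

#' Cohort-level test of a phase delay
#'
#' One-sample t-test of per-subject Gaussian-fit means against 0.
#'
#' @param delays numeric vector of per-subject fitted delays (hours).
#' @return Tibble: `mean_delay_h`, `t`, `df`, `p_value`, `n`.
#' @export
phase_delay_test <- function(delays) {
  tt <- t.test(delays, mu = 0)
  tibble::tibble(
    mean_delay_h = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value, n = length(delays)
  )
}

#' Dependency of one parameter's acute changes on delta-RR
#'
#' Changes between sequential nonempty bins (pairs separated by a gap are
#' skipped) are segregated into delta-RR bins of fixed width, and the mean
#' concurrent change of the other parameter is reported per bin.
#'
#' @param rr,other `binned_series` on the same grid.
#' @param bin_width delta-RR bin width, in the series' units (0.25 SD for
#'   human z-scores, 0.5 SD for mouse).
#' @return A tibble of class `dependency_curve`: `delta_rr_center`,
#'   `mean_delta`, `n`.
#' @export
delta_dependency <- function(rr, other, bin_width = 0.5) {
  if (nrow(rr) != nrow(other)) abort("series must share the bin grid")
  ok <- is.finite(rr$value) & is.finite(other$value)
  consecutive <- ok[-1] & ok[-length(ok)]
  d_rr <- diff(rr$value)[consecutive]
  d_ot <- diff(other$value)[consecutive]
  if (!length(d_rr)) abort("no consecutive nonempty bin pairs")
  lo <- floor(min(d_rr) / bin_width) * bin_width
  hi <- ceiling(max(d_rr) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  if (length(edges) < 2) edges <- c(lo, lo + bin_width)
  idx <- findInterval(d_rr, edges, rightmost.closed = TRUE)
  centers <- edges[-length(edges)] + bin_width / 2
  out <- tibble::tibble(
    delta_rr_center = centers,
    mean_delta = as.numeric(tapply(d_ot, factor(idx, seq_along(centers)),
                                   mean)),
    n = as.integer(table(factor(idx, seq_along(centers))))
  )
  class(out) <- c("dependency_curve", class(out))
  attr(out, "deltas") <- tibble::tibble(d_rr = d_rr, d_other = d_ot)
  out
}

#' Smoothed group-mean profile with SEM band
#'
#' Locally weighted regression (LOWESS) of the across-subject mean profile;
#' the SEM band comes from the subject-level spread per time point.
#'
#' @param profiles tibble with columns `subject`, `time_h`, `value`.
#' @param span LOWESS span (fraction of points).
#' @return Tibble: `time_h`, `mean`, `sem` (`NA` with a single subject),
#'   `smooth`.
#' @export
smooth_profile <- function(profiles, span = 0.3) {
  g <- dplyr::group_by(profiles, .data$time_h)
  s <- dplyr::summarise(
    g,
    mean = mean(.data$value, na.rm = TRUE),
    sem = if (dplyr::n() > 1) sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value)))
          else NA_real_,
    .groups = "drop"
  )
  lw <- lowess(s$time_h, s$mean, f = span)
  s$smooth <- approx(lw$x, lw$y, xout = s$time_h, rule = 2)$y
  s
}

#' Detrend a series by subtracting its centred moving average
#'
#' The moving-average window defaults to 24 h, which removes trends and all
#' harmonics of the daily rhythm's period while (over whole periods) preserving
#' the 24-h component itself. Half a window at each edge is `NA`.
#'
#' @param values regular series.
#' @param dt_h sampling interval (hours).
#' @param window_h moving-average window (hours).
#' @return Numeric vector of detrended values.
#' @export
detrend_moving_average <- function(values, dt_h, window_h = 24) {
  w <- round(window_h / dt_h)
  if (w >= length(values)) abort("series shorter than the window")
  ma <- zoo::rollmean(values, w, fill = NA, align = "center")
  values - ma
}

#' Time-of-day RR-interval distribution heatmap
#'
#' RR intervals across days are binned into 15-min (time-of-day) by 1.5-ms
#' (RR) cells; each time column is converted to the probability of an RR
#' interval falling into each cell, then smoothed with a 2-D Gaussian
#' kernel (SD `smooth_sd` bins, truncated at 3 SD) using circular padding
#' on the time axis and reflection on the RR axis; columns are renormalized
#' to unit mass afterwards.
#'
#' @param time_h times of the RR records (hours; folded modulo 24).
#' @param rr_ms RR intervals (ms).
#' @param time_bin_min time bin width (minutes; 15 gives 96 columns).
#' @param rr_bin_ms RR bin width (ms).
#' @param smooth_sd Gaussian kernel SD in bins (0 disables smoothing).
#' @return An object of class `rr_heatmap`: `prob` matrix (RR bins x time
#'   bins), `time_centers_h`, `rr_centers_ms`, `smoothed`, `empty_cols`.
#' @export
rr_heatmap <- function(time_h, rr_ms, time_bin_min = 15, rr_bin_ms = 1.5,
                       smooth_sd = 5) {
  ok <- is.finite(time_h) & is.finite(rr_ms)
  time_h <- time_h[ok] %% 24; rr_ms <- rr_ms[ok]
  n_t <- as.integer(24 * 60 / time_bin_min)
  t_idx <- pmin(floor(time_h * 60 / time_bin_min) + 1L, n_t)
  r_lo <- floor(min(rr_ms) / rr_bin_ms) * rr_bin_ms
  r_hi <- ceiling(max(rr_ms) / rr_bin_ms) * rr_bin_ms
  r_edges <- seq(r_lo, r_hi, by = rr_bin_ms)
  n_r <- length(r_edges) - 1L
  r_idx <- pmin(findInterval(rr_ms, r_edges, rightmost.closed = TRUE), n_r)
  counts <- matrix(0, n_r, n_t)
  for (i in seq_along(t_idx)) {
    counts[r_idx[i], t_idx[i]] <- counts[r_idx[i], t_idx[i]] + 1
  }
  col_n <- colSums(counts)
  prob <- counts
  nonempty <- col_n > 0
  prob[, nonempty] <- sweep(counts[, nonempty, drop = FALSE], 2,
                            col_n[nonempty], "/")
  smoothed <- FALSE
  if (smooth_sd > 0) {
    prob <- gauss_smooth_2d(prob, smooth_sd)
    cs <- colSums(prob)
    renorm <- cs > 0
    prob[, renorm] <- sweep(prob[, renorm, drop = FALSE], 2, cs[renorm], "/")
    smoothed <- TRUE
  }
  structure(
    list(prob = prob,
         time_centers_h = (seq_len(n_t) - 0.5) * time_bin_min / 60,
         rr_centers_ms = r_edges[-length(r_edges)] + rr_bin_ms / 2,
         smoothed = smoothed, empty_cols = which(!nonempty)),
    class = "rr_heatmap"
  )
}

# Separable 2-D Gaussian smoothing: circular padding along columns (time),
# reflection along rows (RR). Kernel truncated at 3 SD.
gauss_smooth_2d <- function(m, sd_bins) {
  rad <- ceiling(3 * sd_bins)
  k <- exp(-((-rad):rad)^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  n_r <- nrow(m); n_t <- ncol(m)
  # time axis: circular
  idx_t <- ((seq(-rad + 1, n_t + rad) - 1) %% n_t) + 1
  padded <- m[, idx_t, drop = FALSE]
  out_t <- matrix(0, n_r, n_t)
  for (j in seq_len(n_t)) {
    out_t[, j] <- padded[, j:(j + 2 * rad), drop = FALSE] %*% k
  }
  # RR axis: reflection; when the RR range is narrower than the kernel the
  # radius is clamped and the truncated kernel renormalized
  rad_r <- min(rad, n_r - 1L)
  k_r <- exp(-((-rad_r):rad_r)^2 / (2 * sd_bins^2))
  k_r <- k_r / sum(k_r)
  idx_r <- c(rev(seq_len(rad_r) + 1L), seq_len(n_r),
             n_r - seq_len(rad_r))
  padded_r <- out_t[idx_r, , drop = FALSE]
  out <- matrix(0, n_r, n_t)
  for (i in seq_len(n_r)) {
    out[i, ] <- k_r %*% padded_r[i:(i + 2 * rad_r), , drop = FALSE]
  }
  out
}
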