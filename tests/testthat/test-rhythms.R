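# Normalization, binning, cosinor, circular stats, phase delays,
# dependency curves, smoothing, detrending, heatmaps.

test_that("z-scoring uses sample SD of included sweeps and is idempotent", {
  expect_equal(zscore_session(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  expect_equal(zscore_session(x + 5), zscore_session(x))
  z <- zscore_session(x)
  expect_equal(zscore_session(z), z, tolerance = 1e-12)
  # excluded sweeps do not shift the normalization
  x2 <- c(x, 1e6)
  z2 <- zscore_session(x2, include = c(rep(TRUE, 50), FALSE))
  expect_equal(z2[1:50], z)
  expect_error(zscore_session(c(2, 2, 2)), "zero variance")
})

test_that("binning tracks coverage and flags under-covered subjects", {
  t_h <- seq(1 / 24, 24, by = 1 / 12)   # one sweep per 5-min bin
  b <- bin_series(t_h, rnorm(length(t_h)), span_h = 24)
  expect_equal(attr(b, "coverage"), 1)
  expect_false(attr(b, "excluded"))
  expect_true(all(b$n == 1))

  set.seed(91)
  drop <- sample(length(t_h), round(0.35 * length(t_h)))
  b2 <- bin_series(t_h[-drop], rnorm(length(t_h) - length(drop)), span_h = 24)
  expect_true(attr(b2, "excluded"))
  expect_lt(attr(b2, "coverage"), 0.7)
})

test_that("cosinor recovers a noiseless cosine exactly", {
  t_h <- seq(0.25, 48, by = 0.25)
  y <- cosine24(t_h %% 24, mesor = 2, amplitude = 1, acrophase_h = 6)
  f <- cosinor_fit(t_h, y)
  expect_equal(f$amplitude, 1, tolerance = 1e-8)
  expect_equal(f$acrophase_h, 6, tolerance = 1e-8)
  expect_equal(f$mesor, 2, tolerance = 1e-8)
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "acrophase_h"], 6, tolerance = 1e-8)
  expect_lt(glance(f)$p_value, 1e-10)
})

test_that("permutation and F-test agree on an obvious rhythm", {
  set.seed(92)
  t_h <- seq(0.5, 72, by = 0.5)
  y <- cosine24(t_h %% 24, 0, 1, 3) + rnorm(length(t_h), 0, 0.5)
  pf <- cosinor_fit(t_h, y)$p_value
  pp <- cosinor_fit(t_h, y, p_method = "permutation", n_perm = 200)$p_value
  expect_lt(pf, 0.001)
  expect_lt(pp, 0.01)
})

test_that("Watson-Williams matches a permutation oracle and handles wraparound", {
  set.seed(93)
  g1 <- (2 + rnorm(8, 0, 0.5)) %% 24
  g2 <- (14 + rnorm(8, 0, 0.5)) %% 24
  ww <- acrophase_stats(c(g1, g2), rep(c("a", "b"), each = 8))
  expect_lt(ww$p_value, 0.001)
  expect_true(ww$reliable)

  # permutation oracle on the same angles, using the same F statistic
  obs <- ww$statistic
  perm <- replicate(400, {
    acrophase_stats(c(g1, g2), sample(rep(c("a", "b"), each = 8)))$statistic
  })
  p_perm <- (sum(perm >= obs) + 1) / 401
  expect_lt(p_perm, 0.01)

  same <- acrophase_stats(c(g1, g1), rep(c("a", "b"), each = 8))
  expect_gt(same$p_value, 0.9)

  wrap <- acrophase_stats(c(23.5, 0.5, 23.4, 0.6, 12.1, 11.9, 12.2, 11.8),
                          rep(c("a", "b"), each = 4))
  expect_equal(unname(wrap$group_means_h["a"]), 0, tolerance = 0.2)
})

test_that("low-concentration acrophase sets are flagged unreliable", {
  set.seed(94)
  spread <- runif(12, 0, 24)
  ww <- acrophase_stats(spread, rep(c("a", "b"), each = 6))
  expect_false(ww$reliable)
})

test_that("cross-correlogram recovers injected lags on noiseless series", {
  t_h <- seq(1 / 24, 120, by = 1 / 12)
  base <- cosine24(t_h %% 24, 0, 1, 6)
  a <- bin_series(t_h, base, span_h = 120)
  self <- crosscorr_phase(a, a)
  expect_equal(self$delay_h, 0, tolerance = 1 / 12)
  expect_equal(max(self$correlogram$r, na.rm = TRUE), 1, tolerance = 1e-9)

  for (lag in c(0.5, 1.5, 3)) {
    b <- bin_series(t_h, cosine24((t_h - lag) %% 24, 0, 1, 6), span_h = 120)
    pd <- crosscorr_phase(a, b)
    expect_equal(pd$delay_h, lag, tolerance = 1 / 12 + 1e-9)
  }
})

test_that("a flat correlogram has no positive peak and errors", {
  t_h <- seq(1 / 12, 48, by = 1 / 12)
  # opposite linear ramps correlate at exactly -1 at every lag
  a2 <- bin_series(t_h, t_h, span_h = 48)
  b2 <- bin_series(t_h, -t_h, span_h = 48)
  expect_error(crosscorr_phase(a2, b2), "no positive peak")
})

test_that("dependency curve is the identity for self, flat for independence", {
  set.seed(96)
  v <- rnorm(400)
  rb <- tibble::tibble(bin_center_h = seq_along(v) / 12, value = v)
  dc <- delta_dependency(rb, rb, bin_width = 0.5)
  keep <- dc$n >= 5
  expect_equal(dc$mean_delta[keep], dc$delta_rr_center[keep],
               tolerance = 0.3)
  ob <- tibble::tibble(bin_center_h = seq_along(v) / 12, value = rnorm(400))
  dc2 <- delta_dependency(rb, ob, bin_width = 0.5)
  expect_lt(max(abs(dc2$mean_delta[dc2$n >= 20]), na.rm = TRUE), 0.5)
})

test_that("gaps between bins are skipped in the dependency deltas", {
  v <- c(1, 2, NA, 10, 11)
  rb <- tibble::tibble(bin_center_h = 1:5, value = v)
  dc <- delta_dependency(rb, rb, bin_width = 1)
  d <- attr(dc, "deltas")
  expect_equal(nrow(d), 2)            # (1,2) and (10,11) pairs only
  expect_true(all(abs(d$d_rr - 1) < 1e-9))
})

test_that("profile smoothing respects constants and locates the peak", {
  prof <- tidyr::expand_grid(subject = 1:3, time_h = seq(0, 24, by = 0.5))
  prof$value <- 5
  s <- smooth_profile(prof)
  expect_true(all(abs(s$smooth - 5) < 1e-9))

  prof$value <- cosine24(prof$time_h %% 24, 0, 1, 10)
  s2 <- smooth_profile(prof)
  expect_equal(s2$time_h[which.max(s2$smooth)], 10, tolerance = 0.5)

  one <- smooth_profile(prof[prof$subject == 1, ])
  expect_true(all(is.na(one$sem)))
})

test_that("24-h moving-average detrending removes trend, keeps the rhythm", {
  dt_h <- 1 / 12
  t_h <- seq(dt_h, 96, by = dt_h)
  cosv <- cosine24(t_h %% 24, 0, 1, 6)
  d0 <- detrend_moving_average(rep(3, length(t_h)), dt_h)
  expect_true(all(abs(d0) < 1e-12, na.rm = TRUE))

  d1 <- detrend_moving_average(cosv, dt_h)
  keep <- !is.na(d1)
  expect_lt(max(abs(d1[keep] - cosv[keep])), 0.01)

  trended <- cosv + 0.05 * t_h
  d2 <- detrend_moving_average(trended, dt_h)
  f <- cosinor_fit(t_h[!is.na(d2)], d2[!is.na(d2)])
  expect_equal(f$amplitude, 1, tolerance = 0.02)
  expect_lt(abs(f$mesor), 0.05)
})

test_that("heatmap columns are probability masses before and after smoothing", {
  set.seed(97)
  hm0 <- rr_heatmap(runif(2000, 0, 24), rnorm(2000, 100, 3), smooth_sd = 0)
  cs <- colSums(hm0$prob)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))

  # all identical RR: a single cell per column holds mass 1
  hm1 <- rr_heatmap(runif(500, 0, 24), rep(100, 500), smooth_sd = 0)
  expect_true(all(apply(hm1$prob, 2, max)[colSums(hm1$prob) > 0] == 1))

  hm2 <- rr_heatmap(runif(2000, 0, 24), rnorm(2000, 100, 3), smooth_sd = 5)
  expect_true(all(abs(colSums(hm2$prob) - 1) < 1e-9))
})

test_that("time smoothing is circular: rotating the input rotates the map", {
  set.seed(98)
  t_h <- runif(3000, 0, 24)
  rr <- rnorm(3000, 100, 3) + 4 * cos(2 * pi * t_h / 24)
  hm <- rr_heatmap(t_h, rr)
  hm_rot <- rr_heatmap((t_h + 6) %% 24, rr)
  shift <- 6 * 4                       # 6 h in 15-min columns
  rotated <- hm$prob[, ((seq_len(96) - 1 - shift) %% 96) + 1]
  expect_equal(hm_rot$prob, rotated, tolerance = 1e-12)
})
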