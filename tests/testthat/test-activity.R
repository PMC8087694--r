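# Activity coupling: at-rest fit, aligned responses, siesta contrast.

# Truth-level parameter series (sweep medians) for a mouse cohort member.
activity_fixture <- function(gain, noise = c(RR = 0, PRseg = 0, QT = 0),
                             seed = 200, days = 5, tau = 15) {
  sched <- schedule_spec(days = days, species = "mouse",
                         siesta_window = c(20, 22))
  act <- synth_behavior(sched, seed = seed)
  circ <- circadian_params("mouse", noise_sd_ms = noise,
                           activity_gain_ms = gain, activity_tau_min = tau)
  tr <- synth_beat_train(circ, sched, activity = act, seed = seed + 1)
  med <- dplyr::summarise(dplyr::group_by(tr$beats, sweep_id),
                          value = median(rr_ms, na.rm = TRUE),
                          .groups = "drop")
  param <- tibble::tibble(
    t_h = tr$sweeps$t_h,
    value = med$value[match(tr$sweeps$sweep_id, med$sweep_id)]
  )
  list(param = param, act = act, truth = tr, circ = circ)
}

test_that("with no activity coupling the rest fit equals the full-data cosinor", {
  fx <- activity_fixture(gain = 0)
  rf <- at_rest_profile(fx$param, fx$act)
  full <- cosinor_fit(fx$param$t_h, fx$param$value)
  expect_equal(rf$fit$mesor, full$mesor, tolerance = 0.2)
  expect_equal(rf$fit$amplitude, full$amplitude, tolerance = 0.2)
  expect_equal(rf$fit$acrophase_h, full$acrophase_h, tolerance = 0.2)
})

test_that("negative activity gain pushes the full-data mesor below the rest mesor", {
  fx <- activity_fixture(gain = -0.5)
  rf <- at_rest_profile(fx$param, fx$act)
  expect_gt(rf$fit$mesor, mean(fx$param$value))
})

test_that("all-active recordings raise an informative rest-coverage error", {
  fx <- activity_fixture(gain = 0)
  always_on <- fx$act
  always_on$activity <- always_on$activity + 1L
  expect_error(at_rest_profile(fx$param, always_on), "rest")
})

test_that("event selection equals an exhaustive scan of the activity vector", {
  fx <- activity_fixture(gain = -0.5)
  rf <- at_rest_profile(fx$param, fx$act)
  ar <- inactivity_aligned_response(fx$param, fx$act, rf, run_min = 45)
  a <- fx$act$activity
  oracle <- integer(0)
  for (i in 2:length(a)) {
    if (a[i - 1] != 0 && a[i] == 0) {
      hi <- i + 8                      # 45 min = 9 bins including i
      if (hi <= length(a) && all(a[i:hi] == 0)) oracle <- c(oracle, i)
    }
  }
  expect_equal(ar$event_bins, oracle)
})

test_that("aligned response is identically zero without coupling, decays with it", {
  fx0 <- activity_fixture(gain = 0)
  rf0 <- at_rest_profile(fx0$param, fx0$act)
  ar0 <- inactivity_aligned_response(fx0$param, fx0$act, rf0)
  expect_lt(max(abs(ar0$curve$mean), na.rm = TRUE), 0.05)

  fx <- activity_fixture(gain = -0.5, tau = 15)
  rf <- at_rest_profile(fx$param, fx$act)
  ar <- inactivity_aligned_response(fx$param, fx$act, rf)
  cur <- ar$curve
  expect_lt(cur$mean[cur$rel_min == 0], -0.3)        # acute RR shortening
  expect_gt(cur$mean[cur$rel_min == 45], cur$mean[cur$rel_min == 0] / 2)
  last <- cur[cur$rel_min == 45, ]
  expect_lt(abs(last$mean), 2 * last$sem + 0.4)      # decayed back to rest
})

test_that("phase normalization makes day and night events comparable", {
  # pure circadian + fixed activity effect, no noise: deviations should not
  # depend on the clock phase of the event
  fx <- activity_fixture(gain = -0.5)
  rf <- at_rest_profile(fx$param, fx$act)
  dev <- fx$param$value - chronoecg:::predict_rest(rf, fx$param$t_h)
  rest_bins <- rf$rest
  light <- (fx$param$t_h %% 24) < 12
  expect_lt(abs(mean(dev[rest_bins & light]) - mean(dev[rest_bins & !light])),
            0.5)
})

test_that("transient bouts deflect RR but not an uncoupled PR segment", {
  fx <- activity_fixture(gain = -0.5)
  tb <- transient_bout_response(fx$param, fx$act)
  expect_gt(tb$n_events, 5)
  expect_equal(tb$curve$mean[tb$curve$rel_min == -5], 0)   # normalization
  expect_lt(tb$curve$mean[tb$curve$rel_min == 0], -0.2)

  # PR segment generated with zero coupling stays flat
  med_pr <- dplyr::summarise(dplyr::group_by(fx$truth$beats, sweep_id),
                             value = median(prseg_ms, na.rm = TRUE),
                             .groups = "drop")
  pr <- tibble::tibble(
    t_h = fx$truth$sweeps$t_h,
    value = med_pr$value[match(fx$truth$sweeps$sweep_id, med_pr$sweep_id)]
  )
  tbp <- transient_bout_response(pr, fx$act)
  expect_lt(max(abs(tbp$curve$mean), na.rm = TRUE), 0.3)
})

test_that("no-coupling generator yields a flat transient response", {
  fx0 <- activity_fixture(gain = 0)
  tb0 <- transient_bout_response(fx0$param, fx0$act)
  # residual is only the circadian drift across the 25-min window
  expect_lt(max(abs(tb0$curve$mean), na.rm = TRUE), 0.1)
})

test_that("siesta lengthens RR against the preceding active window", {
  fx <- activity_fixture(gain = -0.5)
  sc <- siesta_contrast(fx$param, fx$act, siesta_window = c(20, 22))
  expect_gt(sc$contrast, 2)

  # no siesta: the same contrast is near zero
  sched <- schedule_spec(days = 5, species = "mouse")
  act <- synth_behavior(sched, seed = 300)
  circ <- circadian_params("mouse", noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0),
                           activity_gain_ms = -0.5)
  tr <- synth_beat_train(circ, sched, activity = act, seed = 301)
  med <- dplyr::summarise(dplyr::group_by(tr$beats, sweep_id),
                          value = median(rr_ms, na.rm = TRUE),
                          .groups = "drop")
  p0 <- tibble::tibble(t_h = tr$sweeps$t_h,
                       value = med$value[match(tr$sweeps$sweep_id,
                                               med$sweep_id)])
  sc0 <- siesta_contrast(p0, act, siesta_window = c(20, 22))
  expect_lt(abs(sc0$contrast), abs(sc$contrast) / 2)

  expect_error(
    siesta_contrast(fx$param, fx$act, siesta_window = c(20, 22),
                    comparison_window = c(15, 20)),
    "length"
  )
})
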