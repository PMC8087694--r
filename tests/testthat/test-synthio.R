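# Synthetic generator: beat trains, waveform rendering, behaviour, episodes.

test_that("constant parameters yield exactly constant RR", {
  circ <- circadian_params("mouse",
                           amplitude_ms = c(RR = 0, PRseg = 0, QT = 0),
                           noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0),
                           activity_gain_ms = 0)
  sched <- schedule_spec(days = 1 / 144, species = "mouse") # 10 min
  tr <- synth_beat_train(circ, sched, seed = 1)
  expect_true(all(abs(tr$beats$rr_ms - 100) < 1e-9, na.rm = TRUE))
  expect_true(all(abs(tr$beats$qt_ms - 40) < 1e-9))
})

test_that("telemetry cadence emits 12 sweeps per hour (1440 per 5 days)", {
  sched5 <- schedule_spec(days = 5, species = "mouse")
  expect_length(chronoecg:::schedule_sweep_starts(sched5), 1440)
  hr <- mouse_hour()
  expect_equal(nrow(hr$truth$sweeps), 12)
})

test_that("identical seeds give bit-identical generator output", {
  sched <- schedule_spec(days = 1 / 144, species = "mouse")
  circ <- circadian_params("mouse")
  a <- synth_beat_train(circ, sched, seed = 7)
  b <- synth_beat_train(circ, sched, seed = 7)
  expect_identical(a$beats, b$beats)
  ra <- synth_ecg_waveform(a, morphology_profile("mouse"), seed = 8)
  rb <- synth_ecg_waveform(b, morphology_profile("mouse"), seed = 8)
  expect_identical(ra$sweeps$samples, rb$sweeps$samples)
})

test_that("PRseg acrophase offset appears as a lagged-correlation peak", {
  # noiseless intervals; brute-force lagged Pearson correlation as oracle
  circ <- circadian_params("mouse",
                           acrophase_h = c(RR = 6, PRseg = 7.5),
                           noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0),
                           activity_gain_ms = 0)
  sched <- schedule_spec(days = 3, species = "mouse")
  tr <- synth_beat_train(circ, sched, seed = 3)
  med <- dplyr::summarise(dplyr::group_by(tr$beats, sweep_id),
                          rr = median(rr_ms, na.rm = TRUE),
                          pr = median(prseg_ms, na.rm = TRUE),
                          .groups = "drop")
  step_h <- 1 / 12
  lags <- -36:36                       # +/- 3 h in 5-min steps
  r <- vapply(lags, function(k) {
    n <- nrow(med)
    if (k >= 0) cor(med$rr[seq_len(n - k)], med$pr[seq_len(n - k) + k])
    else cor(med$rr[seq_len(n + k) - k], med$pr[seq_len(n + k)])
  }, numeric(1))
  expect_equal(lags[which.max(r)] * step_h, 1.5, tolerance = step_h + 1e-9)
})

test_that("rendered annotations conserve the true intervals to one sample", {
  hr <- mouse_hour()
  a <- hr$rec$annotations
  b <- hr$truth$beats
  rr_ann <- stats::ave(a$r_sample, a$sweep_id,
                       FUN = function(z) c(NA, diff(z)))
  expect_lt(max(abs(rr_ann - b$rr_ms), na.rm = TRUE), 1 + 1e-9)
  expect_lt(max(abs((a$t_off_sample - a$q_on_sample) - b$qt_ms),
                na.rm = TRUE), 1 + 1e-9)
  expect_lt(max(abs((a$q_on_sample - a$p_off_sample) - b$prseg_ms),
                na.rm = TRUE), 1 + 1e-9)
})

test_that("clean single-beat properties: R at argmax, mouse T a local minimum", {
  circ <- circadian_params("mouse", noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0))
  sched <- schedule_spec(days = 1 / 8640, species = "mouse") # one sweep
  tr <- synth_beat_train(circ, sched, seed = 5)
  rec <- synth_ecg_waveform(tr, morphology_profile("mouse"), fs = 1000,
                            seed = 6, noise_sd = 0, baseline_wander_amp = 0)
  x <- rec$sweeps$samples[[1]]
  a <- rec$annotations
  expect_equal(which.max(x[1:60]), a$r_sample[1])
  tp <- a$t_peak_sample[2]
  expect_true(x[tp] <= x[tp - 1] && x[tp] <= x[tp + 1])   # local minimum
  expect_lt(x[tp], 0)
})

test_that("a 50-ms QT renders as a 50-sample Q-onset-to-T-offset span at 1 kHz", {
  circ <- circadian_params("mouse",
                           mesor_ms = c(QT = 50),
                           amplitude_ms = c(RR = 0, PRseg = 0, QT = 0),
                           noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0))
  sched <- schedule_spec(days = 1 / 8640, species = "mouse")
  tr <- synth_beat_train(circ, sched, seed = 9)
  rec <- synth_ecg_waveform(tr, morphology_profile("mouse"), fs = 1000,
                            seed = 10, noise_sd = 0)
  a <- rec$annotations
  expect_true(all(abs((a$t_off_sample - a$q_on_sample) - 50) <= 1))
})

test_that("behaviour: siesta lowers activity; acrophase fixed without a shift", {
  sched <- schedule_spec(days = 4, species = "mouse", siesta_window = c(20, 22))
  act <- synth_behavior(sched, seed = 21)
  in_siesta <- act$zt_h >= 20 & act$zt_h < 22
  before <- act$zt_h >= 18 & act$zt_h < 20
  expect_lt(mean(act$activity[in_siesta]), mean(act$activity[before]))
  acro <- vapply(0:3, function(d) {
    sub <- act[act$t_h >= d * 24 & act$t_h < (d + 1) * 24, ]
    cosinor_fit(sub$t_h %% 24, sub$activity)$acrophase_h
  }, numeric(1))
  expect_lt(max(abs(acro - mean(acro))), 1)
})

test_that("behaviour re-entrains at the configured rate after a 9-h advance", {
  sched <- schedule_spec(days = 9, species = "mouse", phase_shift_day = 3,
                         shift_hours = 9, reentrain_rate_h_per_day = 1.5)
  act <- synth_behavior(sched, seed = 22)
  acro <- vapply(0:8, function(d) {
    sub <- act[act$t_h >= d * 24 & act$t_h < (d + 1) * 24, ]
    cosinor_fit(sub$t_h %% 24, sub$activity)$acrophase_h
  }, numeric(1))
  drift <- -diff(acro[4:9])            # daily advance after the shift day
  expect_true(all(abs(drift - 1.5) < 0.8))
  expect_lt(abs(acro[1] - acro[2]), 1) # stable before the shift
})

test_that("episode injection obeys the 4-beat rule and alternation", {
  hr <- mouse_hour()
  tr <- synth_arrhythmia_episode(hr$truth, "BVT", 4, seed = 31)
  expect_equal(nrow(tr$episodes), 1)
  expect_equal(tr$episodes$n_beats, 4L)
  expect_equal(tr$episodes$kind, "BVT")
  vpc <- tr$beats[tr$beats$label == "VPC", ]
  expect_equal(nrow(vpc), 4)
  signs <- sign(vpc$amp_factor)
  expect_true(all(signs[-1] != signs[-length(signs)]))

  tr3 <- synth_arrhythmia_episode(hr$truth, "VT", 3, seed = 32)
  expect_equal(nrow(tr3$episodes), 0)
  expect_equal(sum(tr3$beats$label == "VPC"), 3)
})

test_that("non-positive interval settings are rejected", {
  circ <- circadian_params("mouse", mesor_ms = c(RR = 3),
                           noise_sd_ms = c(RR = 30))
  sched <- schedule_spec(days = 1 / 144, species = "mouse")
  expect_error(synth_beat_train(circ, sched, seed = 1), "non-positive|1%")
})
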