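# R-peak detection, template filtering, and the three QC rules.

test_that("an all-zero sweep yields no candidates", {
  cand <- detect_r_peaks(rep(0, 10000), fs = 1000, species = "mouse",
                         window = amplitude_window(0.1, 1))
  expect_length(cand, 0)
})

test_that("detection matches a brute-force windowed-argmax oracle on clean trains", {
  circ <- circadian_params("mouse", noise_sd_ms = c(RR = 0, PRseg = 0, QT = 0))
  sched <- schedule_spec(days = 1 / 8640, species = "mouse")
  tr <- synth_beat_train(circ, sched, seed = 51)
  rec <- synth_ecg_waveform(tr, morphology_profile("mouse"), fs = 1000,
                            seed = 52, noise_sd = 0, baseline_wander_amp = 0)
  x <- rec$sweeps$samples[[1]]
  truth_r <- rec$annotations$r_sample
  cand <- detect_r_peaks(x, 1000, "mouse")
  # oracle: the argmax of |x| inside +/-25 ms of each true beat
  oracle <- vapply(truth_r, function(r) {
    win <- max(1, r - 25):min(length(x), r + 25)
    win[which.max(abs(x[win]))]
  }, integer(1))
  expect_identical(as.integer(cand), oracle)
})

test_that("refractory keeps the larger peak, ties to the earlier sample", {
  t_ms <- (0:999)
  two <- chronoecg:::gaussian_bumps(t_ms, c(400, 430), c(2.5, 2.5), c(1, 0.8))
  cand <- detect_r_peaks(two, 1000, "mouse",
                         window = amplitude_window(0.3, 2))
  expect_equal(as.integer(cand), 401)
  # equal amplitudes: earlier wins
  tie <- chronoecg:::gaussian_bumps(t_ms, c(400, 430), c(2.5, 2.5), c(1, 1))
  cand <- detect_r_peaks(tie, 1000, "mouse",
                         window = amplitude_window(0.3, 2))
  expect_equal(as.integer(cand), 401)
})

test_that("template filter keeps identical beats and drops an inverted one", {
  r_times <- seq(500, 9500, by = 100)
  bumps <- mouse_bumps(r_times)
  x <- render_sweep(bumps[, 1], bumps[, 2], bumps[, 3])
  cand <- detect_r_peaks(x, 1000, "mouse")
  bs <- template_filter(x, as.integer(cand), 1000, "mouse")
  expect_true(all(bs$included))
  expect_lt(max(bs$mismatch, na.rm = TRUE), 1e-6)

  # invert one beat's QRS
  inv <- bumps
  bad <- which(bumps[, 1] %in% c(5000 - 6, 5000, 5000 + 5))
  inv[bad, 3] <- -inv[bad, 3]
  x2 <- render_sweep(inv[, 1], inv[, 2], inv[, 3])
  cand2 <- detect_r_peaks(x2, 1000, "mouse")
  bs2 <- template_filter(x2, as.integer(cand2), 1000, "mouse")
  excluded_at <- bs2$candidates[!bs2$included]
  expect_true(any(abs(excluded_at - 5001) < 10))
  expect_equal(sum(!bs2$included), 1)
})

test_that("rejection fraction is plain arithmetic over candidates", {
  bs <- structure(list(candidates = 1:8, included = c(rep(TRUE, 6), FALSE,
                                                      FALSE),
                       mismatch = rep(0, 8), template = NULL, half_w = 10,
                       rejection_fraction = 2 / 8, flagged = FALSE),
                  class = "beat_set")
  expect_equal(bs$rejection_fraction, 0.25)
})

test_that("QC rule boundaries: 3x lower amplitude, 1/3 lower baseline, 20% rejection", {
  fs <- 1000
  win <- amplitude_window(0.2, 2)
  make_sweep <- function(amp, spread = 0.001) {
    r_times <- seq(500, 9500, by = 100)
    bumps <- qrs_bumps(r_times, amp = amp)
    x <- render_sweep(bumps[, 1], bumps[, 2], bumps[, 3])
    w <- sin(2 * pi * seq_along(x) / 777)
    in_beat <- rep(FALSE, length(x))
    for (r in r_times + 1) {
      in_beat[max(1, r - 40):min(length(x), r + 40)] <- TRUE
    }
    # scale the wiggle so the baseline MAD spread is exactly `spread`
    x + w * spread / mad(w[!in_beat])
  }
  run_qc <- function(x, rejection = NULL) {
    cand <- detect_r_peaks(x, fs, "mouse", window = win)
    bs <- template_filter(x, as.integer(cand), fs, "mouse")
    if (!is.null(rejection)) bs$rejection_fraction <- rejection
    sweep_qc(x, bs, win)
  }
  # rule 1: mean beat amplitude vs 3 x lower (= 0.6 mV here)
  expect_false(run_qc(make_sweep(0.58))$pass)           # 2.9 x lower
  expect_match(run_qc(make_sweep(0.58))$rule_failures, "low_amplitude")
  expect_true(run_qc(make_sweep(0.62))$pass)            # 3.1 x lower

  # rule 2: baseline variation vs lower / 3 (= 0.0667 mV)
  qc_hi <- run_qc(make_sweep(1, spread = 0.34 * win$lower))
  expect_false(qc_hi$pass)
  expect_match(qc_hi$rule_failures, "baseline_noise")
  expect_true(run_qc(make_sweep(1, spread = 0.30 * win$lower))$pass)

  # rule 3: rejection fraction vs 20%
  expect_false(run_qc(make_sweep(1), rejection = 0.25)$pass)
  expect_match(run_qc(make_sweep(1), rejection = 0.25)$rule_failures,
               "high_rejection")
  expect_true(run_qc(make_sweep(1), rejection = 0.19)$pass)

  # no beats at all -> low_amplitude failure
  empty <- structure(list(candidates = integer(0), included = logical(0),
                          mismatch = numeric(0), template = NULL,
                          half_w = 40, rejection_fraction = 0,
                          flagged = TRUE),
                     class = "beat_set")
  qc0 <- sweep_qc(rep(0.001, 10000), empty, win)
  expect_false(qc0$pass)
  expect_match(qc0$rule_failures, "low_amplitude")
})

test_that("beat processing is deterministic for a fixed sweep and config", {
  hr <- mouse_hour()
  x <- hr$rec$sweeps$samples[[5]]
  b1 <- template_filter(x, as.integer(detect_r_peaks(x, 1000, "mouse")),
                        1000, "mouse")
  b2 <- template_filter(x, as.integer(detect_r_peaks(x, 1000, "mouse")),
                        1000, "mouse")
  expect_identical(b1$included, b2$included)
  expect_identical(b1$mismatch, b2$mismatch)
})

test_that("detected beat count equals truth on every clean sweep", {
  hr <- mouse_hour()
  counts <- vapply(seq_len(12), function(k) {
    length(detect_r_peaks(hr$rec$sweeps$samples[[k]], 1000, "mouse"))
  }, integer(1))
  expect_equal(counts, hr$truth$sweeps$n_beats)
})

test_that("increasing baseline noise never flips a failing sweep to passing", {
  hr <- mouse_hour()
  x <- hr$rec$sweeps$samples[[1]]
  win <- amplitude_window(0.25, 2)
  wander <- seq(0, 0.4, by = 0.05)
  t_s <- (seq_along(x) - 1) / 1000
  pass <- vapply(wander, function(a) {
    xa <- x + a * sin(2 * pi * t_s / 1.3)
    cand <- detect_r_peaks(xa, 1000, "mouse", window = win)
    bs <- template_filter(xa, as.integer(cand), 1000, "mouse")
    sweep_qc(xa, bs, win)$pass
  }, logical(1))
  expect_true(all(diff(pass) <= 0))   # monotone: once failing, stays failing
})
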