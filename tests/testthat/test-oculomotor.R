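test_that("the low-pass filter passes DC and attenuates high frequencies", {
  t <- seq(0, 998, by = 2)
  const <- data.frame(time_ms = t, x_deg = rep(3.2, length(t)))
  expect_lt(max(abs(filter_trace(const)$x_deg - 3.2)), 1e-9)
  # 200 Hz sinusoid against a 50 Hz cutoff
  sine <- data.frame(time_ms = t, x_deg = sin(2 * pi * 200 * t / 1000))
  filt <- filter_trace(sine, cutoff_hz = 50)
  core <- seq(50, length(t) - 50)     # ignore filter edge transients
  expect_lt(max(abs(filt$x_deg[core])), 0.05)
  expect_error(filter_trace(const[1:5, ]), "shorter")
})

test_that("filtered velocity reproduces the generator's analytic peak", {
  tr <- generate_eye_trace(14, 0)
  ft <- filter_trace(tr$trace)
  expect_lt(abs(max(abs(ft$v_degs)) - tr$truth$peak_velocity) /
              tr$truth$peak_velocity, 0.05)
})

test_that("detection recovers the threshold crossing of a noiseless trace", {
  for (amp in c(12, -14, 16)) {
    tr <- generate_eye_trace(amp, start_position = -sign(amp) * 6)
    ev <- detect_saccade(filter_trace(tr$trace))
    dt <- 1000 / tr$truth$sampling_rate
    expect_lte(abs(ev$onset_ms - tr$truth$thr_onset_ms), dt)
    expect_lte(abs(ev$offset_ms - tr$truth$thr_offset_ms), 2 * dt)
    expect_lt(abs(ev$amplitude - amp), 0.05)
    expect_false(ev$multiple)
  }
})

test_that("a subthreshold trace raises a no-saccade error", {
  t <- seq(0, 998, by = 2)
  slow <- data.frame(time_ms = t, x_deg = 0.01 * t / 1000)  # 0.01 deg/s drift
  expect_error(detect_saccade(filter_trace(slow)), "no saccade")
})

test_that("a corrective saccade is flagged and the principal event returned", {
  main <- generate_eye_trace(14, 0)$trace
  corr <- generate_eye_trace(-11, 14)$trace   # large enough to supra-threshold
  corr$time_ms <- corr$time_ms + max(main$time_ms) + 2
  two <- rbind(main, corr)
  ev <- detect_saccade(filter_trace(two))
  expect_true(ev$multiple)
  expect_gt(ev$amplitude, 12)     # principal = the 14 degree movement
})

test_that("detection commutes with position and time shifts", {
  tr <- generate_eye_trace(13, 2)$trace
  ev0 <- detect_saccade(filter_trace(tr))
  shifted <- data.frame(time_ms = tr$time_ms + 100, x_deg = tr$x_deg + 5)
  ev1 <- detect_saccade(filter_trace(shifted))
  expect_equal(ev1$onset_ms, ev0$onset_ms + 100)
  expect_equal(ev1$start_position, ev0$start_position + 5, tolerance = 1e-9)
  expect_equal(ev1$amplitude, ev0$amplitude, tolerance = 1e-9)
})

test_that("noisy round-trip amplitudes are accurate in at least 95% of trials", {
  rng <- sacdisp:::new_rng(123)
  n <- 500
  ok <- logical(n)
  for (i in seq_len(n)) {
    amp <- rng$runif(1, 10, 16) * (if (rng$runif(1) < 0.5) -1 else 1)
    tr <- generate_eye_trace(amp, 0, noise_sd = 0.05, rng = rng)
    ev <- detect_saccade(filter_trace(tr$trace))
    ok[i] <- abs(ev$amplitude - amp) < 0.2
  }
  expect_gte(mean(ok), 0.95)
})

test_that("targeting metrics follow the stated arithmetic and conventions", {
  trials <- data.frame(
    condition = "STEP", direction = "rightward",
    fixation_position = c(-6, -6),
    target_position = c(8, 8),
    stimulus_amplitude = c(14, 14),
    saccade_landing = c(7.0, 8.0))
  tm <- targeting_metrics(trials)
  expect_equal(tm$trials$gain, c(13 / 14, 1))
  expect_equal(tm$trials$targeting_error, c(-1.0, 0))
  expect_equal(tm$trials$hypometria_error, -tm$trials$targeting_error)
  expect_equal(tm$summary$n_excluded, 0L)
})

test_that("cohort mean gain reproduces the generating motor gain", {
  cfg <- task_config("STEP", "rightward")
  p <- observer_params(motor_gain = 0.9, motor_sd = 0)
  tb <- simulate_session(cfg, p, seed = 6)
  tm <- targeting_metrics(tb)
  expect_lt(abs(tm$summary$gain - 0.9), 1e-6)
})

test_that("missing landings and wrong-way saccades are excluded and counted", {
  trials <- data.frame(
    condition = "STEP", direction = "rightward",
    fixation_position = rep(-6, 3),
    target_position = rep(8, 3),
    stimulus_amplitude = rep(14, 3),
    saccade_landing = c(7, NA, -10))   # one missing, one leftward
  tm <- targeting_metrics(trials)
  expect_equal(tm$summary$n, 1L)
  expect_equal(tm$summary$n_excluded, 2L)
})

test_that("trigger timing is summarised against the saccade midpoint", {
  events <- data.frame(onset_ms = c(300, 300), offset_ms = c(350, 350))
  tc <- trigger_check(events, c(319, 352))
  expect_equal(tc$fraction_before_midpoint, 0.5)
  expect_equal(tc$flagged, 2L)
  expect_equal(tc$delay_mean_ms, mean(c(19, 52)))
  # simulator defaults put every trigger in the first half of the saccade
  rng <- sacdisp:::new_rng(5)
  evs <- lapply(1:25, function(i) {
    tr <- generate_eye_trace(14, 0, noise_sd = 0.05, rng = rng)
    list(ev = detect_saccade(filter_trace(tr$trace)),
         trig = tr$truth$trigger_ms)
  })
  tc2 <- trigger_check(lapply(evs, `[[`, "ev"),
                       vapply(evs, `[[`, numeric(1), "trig"))
  expect_equal(tc2$fraction_before_midpoint, 1)
})
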