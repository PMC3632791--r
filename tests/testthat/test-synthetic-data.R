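test_that("simulated saccade amplitude follows the motor model", {
  rng <- sacdisp:::new_rng(1)
  p0 <- observer_params(motor_gain = 1, motor_sd = 0)
  expect_equal(simulate_saccade(14, p0, rng)$executed_amplitude, 14)
  p1 <- observer_params(motor_gain = 0.9, motor_sd = 0)
  s <- simulate_saccade(14, p1, rng)
  expect_equal(s$executed_amplitude, 12.6)
  expect_equal(s$executed_amplitude - 14, -1.4)
  # leftward stimuli land leftward
  expect_lt(simulate_saccade(-14, p1, rng)$amplitude, 0)
})

test_that("Monte-Carlo mean gain matches the motor gain", {
  rng <- sacdisp:::new_rng(99)
  p <- observer_params(motor_gain = 0.94, motor_sd = 1)
  gains <- replicate(1e4, simulate_saccade(14, p, rng)$executed_amplitude / 14)
  expect_lt(abs(mean(gains) - 0.94), 0.01)
})

test_that("the percept stage realises the three monitoring mechanisms", {
  rng <- sacdisp:::new_rng(1)
  noiseless <- function(...) observer_params(motor_sd = 0, cd_sd = 0,
                                             decision_sd_step = 0,
                                             decision_sd_blank = 0, ...)
  # intact observer sees the true displacement
  p <- noiseless(motor_gain = 1)
  sacc <- simulate_saccade(14, p, rng)
  expect_equal(simulate_percept(1, sacc, 14, "BLANK", p, rng), "forward")
  expect_equal(simulate_percept(-1, sacc, 14, "BLANK", p, rng), "backward")
  # hypometric CD: internal underestimation biases toward backward reports
  ph <- noiseless(motor_gain = 1, cd_gain = 0.9)
  sacch <- simulate_saccade(14, ph, rng)
  expect_equal(simulate_percept(0, sacch, 14, "BLANK", ph, rng), "backward")
  # uncoupled CD: a self-generated undershoot is read as a forward jump
  pl <- observer_params(motor_gain = 1, motor_sd = 1, cd_sd = 0,
                        cd_coupling = 0, decision_sd_blank = 0)
  sacc_short <- list(executed_amplitude = 13, motor_error = -1)
  expect_equal(simulate_percept(0, sacc_short, 14, "BLANK", pl, rng),
               "forward")
})

test_that("session simulation is deterministic and sized by the design", {
  cfg <- task_config("BLANK", "leftward", blocks = 5)
  t1 <- simulate_session(cfg, observer_preset("control"), seed = 5)
  t2 <- simulate_session(cfg, observer_preset("control"), seed = 5)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 120L)
  expect_true(all(t1$report %in% c("forward", "backward")))
  expect_true(all(is.finite(t1$saccade_landing)))
})

test_that("hypometric CD shifts the fitted PSS forward; hypermetric backward", {
  hypo <- observer_params(cd_gain = 0.9, cd_sd = 0.2)
  hyper <- observer_params(cd_gain = 1.1, cd_sd = 0.2)
  tb_hypo <- sim_blank_trials(hypo, seed = 3, n_blocks = 6)
  tb_hyper <- sim_blank_trials(hyper, seed = 3, n_blocks = 6)
  f_hypo <- fit_cumulative_gaussian(tb_hypo$displacement, tb_hypo$report)
  f_hyper <- fit_cumulative_gaussian(tb_hyper$displacement, tb_hyper$report)
  expect_gt(f_hypo$pss, 0)
  expect_lt(f_hyper$pss, 0)
})

test_that("motor-error coupling controls the trial-level error-report correlation", {
  for (lam in c(0, 1)) {
    p <- observer_params(cd_coupling = lam, cd_sd = 0.2)
    tb <- sim_blank_trials(p, seed = 17)
    tb <- tb[seq_len(2000), ]
    r <- cor(tb$motor_error, as.integer(tb$report == "forward"))
    if (lam == 1) expect_lt(abs(r), 0.05) else expect_lt(r, -0.2)
  }
})

test_that("synthetic eye traces have the constructed geometry", {
  tr <- generate_eye_trace(14, start_position = -6)
  x <- tr$trace$x_deg
  t <- tr$trace$time_ms
  on <- tr$truth$movement_onset_ms
  off <- tr$truth$movement_offset_ms
  expect_lt(abs((x[which.min(abs(t - off))] - x[which.min(abs(t - on))]) - 14),
            1e-6)
  expect_gt(tr$truth$peak_velocity, 30)
  expect_gte(on, 200)
  expect_gte(max(t) - off, 250)
  # trigger one display frame after the threshold crossing lands in the
  # first half of the saccade
  expect_lt(tr$truth$trigger_ms, (on + off) / 2)
})

test_that("lesion cohorts plant the critical region as specified", {
  spec <- lesion_cohort_spec()
  co <- generate_lesion_cohort(spec, seed = 2)
  expect_equal(co$impaired, co$true_overlap)   # noise 0: labels = overlap
  expect_gte(sum(co$true_overlap), 2)
  crit <- critical_region_mask(spec)
  for (p in seq_along(co$masks)) {
    expect_equal(co$true_overlap[p], any(co$masks[[p]] & crit))
  }
  expect_error(lesion_cohort_spec(critical_centre_mm = c(100, 0, 0)),
               "outside the grid")
})

test_that("a cohort with uniform labels yields an empty lesion-symptom map", {
  spec <- lesion_cohort_spec(n_patients = 6)
  co <- generate_lesion_cohort(spec, seed = 4)
  co$impaired <- rep(FALSE, 6)
  vl <- vlsm_map(co)
  expect_true(vl$empty)
  expect_equal(vl$n_included, 0L)
})

test_that("lesion cohorts round-trip through NIfTI and the label table", {
  spec <- lesion_cohort_spec(n_patients = 4, grid_shape = c(16L, 16L, 16L),
                             origin_mm = c(-8, -22, -4),
                             critical_centre_mm = c(0, -15, 2),
                             centre_sd = 2, lesion_radius_range = c(2, 3))
  co <- generate_lesion_cohort(spec, seed = 8)
  dir <- withr::local_tempdir()
  write_lesion_cohort(co, dir)
  paths <- file.path(dir, paste0(co$patient_ids, ".nii.gz"))
  co2 <- read_lesion_cohort(paths, file.path(dir, "labels.csv"))
  for (p in 1:4) expect_equal(co2$masks[[p]], co$masks[[p]])
  expect_equal(co2$impaired, co$impaired)
  expect_equal(co2$affine[1:3, 4], spec$origin_mm,
               ignore_attr = TRUE)
})
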