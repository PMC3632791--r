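#' Generative observer parameters for corollary-discharge monitoring
#'
#' The observer executes a saccade of amplitude `S = g * |A| + eps_m` toward a
#' stimulus of amplitude `A` (motor gain `g`, trial-to-trial motor noise
#' `eps_m ~ N(0, motor_sd^2)`). Its internal corollary-discharge (CD) estimate
#' of the executed amplitude is
#' `S_hat = cd_gain * (g * |A| + cd_coupling * eps_m) + eps_cd`:
#' `cd_gain < 1` is a hypometric CD (the eye moved farther than the brain
#' believes), `cd_coupling` is the fraction of the trial's motor error that
#' the CD captures (1 = intact monitoring, 0 = the observer cannot tell its
#' own targeting error from a target jump). The perceived displacement is
#' `D_hat = D + (S_hat - S)` and the report is forward when
#' `w * D_hat + eps_dec >= 0`, with condition-specific decision noise
#' (`decision_sd_step > decision_sd_blank` encodes saccadic suppression of
#' displacement) and an optional down-weighting `w` of visual evidence. With
#' probability `lapse_rate` the report is replaced by a fair coin flip.
#'
#' @param motor_gain Saccadic amplitude gain (executed / stimulus amplitude).
#' @param motor_sd SD of trial-to-trial motor error, degrees.
#' @param cd_gain CD gain (1 intact, < 1 hypometric CD, > 1 hypermetric).
#' @param cd_sd SD of CD noise, degrees.
#' @param cd_coupling Fraction of motor error captured by the CD, in [0, 1].
#' @param decision_sd_step,decision_sd_blank Decision noise SD per condition,
#'   degrees.
#' @param weight_step,weight_blank Reliance weight on the perceived
#'   displacement per condition, in [0, 1].
#' @param lapse_rate Probability of a stimulus-independent guess.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(motor_gain = 0.92, motor_sd = 1.0,
                            cd_gain = 1.0, cd_sd = 0.3, cd_coupling = 1.0,
                            decision_sd_step = 1.8, decision_sd_blank = 0.4,
                            weight_step = 1.0, weight_blank = 1.0,
                            lapse_rate = 0.0) {
  stopifnot(motor_gain > 0, cd_gain > 0,
            motor_sd >= 0, cd_sd >= 0,
            decision_sd_step >= 0, decision_sd_blank >= 0,
            cd_coupling >= 0, cd_coupling <= 1,
            weight_step >= 0, weight_step <= 1,
            weight_blank >= 0, weight_blank <= 1,
            lapse_rate >= 0, lapse_rate <= 1)
  structure(list(motor_gain = motor_gain, motor_sd = motor_sd,
                 cd_gain = cd_gain, cd_sd = cd_sd, cd_coupling = cd_coupling,
                 decision_sd_step = decision_sd_step,
                 decision_sd_blank = decision_sd_blank,
                 weight_step = weight_step, weight_blank = weight_blank,
                 lapse_rate = lapse_rate),
            class = "observer_params")
}

#' Shipped observer presets
#'
#' `"control"` is an intact monitor (CD gain 1, full error coupling, a strong
#' reduction of decision noise under blanking). `"thalamic"` is a lesion-like
#' observer with a hypometric CD (gain 0.9), no coupling of the CD to the
#' trial's motor error (the error-attribution failure), and noisier CD. The
#' presets are illustrative parameterisations of the two qualitative
#' phenotypes, not fits to patient data.
#'
#' @param name `"control"` or `"thalamic"`.
#' @return An `observer_params` object.
#' @export
observer_preset <- function(name = c("control", "thalamic")) {
  name <- match.arg(name)
  switch(name,
    control = observer_params(),
    thalamic = observer_params(cd_gain = 0.90, cd_sd = 0.6, cd_coupling = 0,
                               motor_gain = 0.92, motor_sd = 1.0))
}

#' Simulate one saccade
#'
#' @param stimulus_amplitude Signed stimulus amplitude in screen degrees
#'   (negative = leftward); magnitude in [10, 20].
#' @param params An `observer_params`.
#' @param rng A private RNG stream from `new_rng()`.
#' @return A list with `executed_amplitude` (positive degrees),
#'   `motor_error`, `planned_amplitude`, and the signed `amplitude` in screen
#'   coordinates.
#' @export
simulate_saccade <- function(stimulus_amplitude, params, rng) {
  A <- abs(stimulus_amplitude)
  stopifnot(A >= 10, A <= 20)
  eps_m <- if (params$motor_sd > 0) rng$rnorm(1, 0, params$motor_sd) else 0
  S <- params$motor_gain * A + eps_m
  sgn <- sign(stimulus_amplitude)
  list(planned_amplitude = params$motor_gain * A,
       executed_amplitude = S,
       motor_error = eps_m,
       amplitude = sgn * S)
}

#' Simulate one perceptual report
#'
#' @param displacement Target displacement in degrees, forward-positive.
#' @param saccade Result of `simulate_saccade()` for this trial.
#' @param stimulus_amplitude Signed stimulus amplitude, degrees.
#' @param condition `"STEP"` or `"BLANK"`.
#' @param params An `observer_params`.
#' @param rng A private RNG stream.
#' @return `"forward"` or `"backward"`.
#' @export
simulate_percept <- function(displacement, saccade, stimulus_amplitude,
                             condition, params, rng) {
  A <- abs(stimulus_amplitude)
  eps_cd <- if (params$cd_sd > 0) rng$rnorm(1, 0, params$cd_sd) else 0
  S_hat <- params$cd_gain *
    (params$motor_gain * A + params$cd_coupling * saccade$motor_error) + eps_cd
  D_hat <- displacement + (S_hat - saccade$executed_amplitude)
  sd_dec <- if (condition == "STEP") params$decision_sd_step else params$decision_sd_blank
  w <- if (condition == "STEP") params$weight_step else params$weight_blank
  eps_dec <- if (sd_dec > 0) rng$rnorm(1, 0, sd_dec) else 0
  report <- if (w * D_hat + eps_dec >= 0) "forward" else "backward"
  if (params$lapse_rate > 0 && rng$runif(1) < params$lapse_rate) {
    report <- if (rng$runif(1) < 0.5) "forward" else "backward"
  }
  report
}

#' Simulate a full session of the displacement task
#'
#' Composes `schedule_session()`, `simulate_saccade()`, the staircase engine
#' and `simulate_percept()` into a complete trial table for one condition and
#' direction. Displacements are forward-positive relative to saccade
#' direction; saccade landing is recorded in screen coordinates; the
#' per-trial motor error is kept for downstream error-attribution binning.
#' Trigger delays after saccade onset are drawn to mimic gaze-contingent
#' display updates (mean 19 ms, SD 4 ms, truncated positive).
#'
#' @param config A `task_config`.
#' @param params An `observer_params`, or a named list with elements
#'   `leftward` and `rightward` for direction-specific observers.
#' @param seed Integer seed.
#' @return A trial table (data frame), one row per trial.
#' @export
simulate_session <- function(config, params, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  if (inherits(params, "observer_params")) {
    p <- params
  } else {
    p <- params[[config$direction]]
    stopifnot(inherits(p, "observer_params"))
  }
  sched <- schedule_session(config, seed = seed)
  rng <- new_rng(seed + 104729L)   # independent stream for the observer
  stairs <- lapply(1:3, function(i)
    staircase(config$staircase_starts[i], config$step_size, id = i))
  n <- nrow(sched)
  displacement <- report <- landing <- motor_error <- trigger <- numeric(n)
  report <- character(n)
  for (i in seq_len(n)) {
    sc <- sched$staircase_id[i]
    D <- stairs[[sc]]$level
    sacc <- simulate_saccade(sched$stimulus_amplitude[i], p, rng)
    rep_i <- simulate_percept(D, sacc, sched$stimulus_amplitude[i],
                              config$condition, p, rng)
    stairs[[sc]] <- staircase_update(stairs[[sc]], rep_i)
    displacement[i] <- D
    report[i] <- rep_i
    landing[i] <- sched$fixation_position[i] + sacc$amplitude
    motor_error[i] <- sacc$motor_error
    trigger[i] <- max(1, rng$rnorm(1, 19, 4))
  }
  out <- sched
  out$displacement <- displacement
  out$report <- report
  out$saccade_landing <- landing
  out$motor_error <- motor_error
  out$trigger_delay_ms <- trigger
  out
}

#' Simulate a subject across both conditions and directions
#'
#' @param params An `observer_params` or a named list with `leftward` and
#'   `rightward` entries.
#' @param seed Integer seed (sub-seeds are derived per condition x direction).
#' @param blocks Blocks per condition and direction (5 or 6).
#' @return A trial table covering STEP and BLANK, leftward and rightward.
#' @export
simulate_subject <- function(params, seed = 1L, blocks = 5) {
  cells <- expand.grid(condition = c("STEP", "BLANK"),
                       direction = c("leftward", "rightward"),
                       stringsAsFactors = FALSE)
  tabs <- lapply(seq_len(nrow(cells)), function(k) {
    cfg <- task_config(condition = cells$condition[k],
                       direction = cells$direction[k], blocks = blocks)
    simulate_session(cfg, params, seed = as.integer(seed) * 8L + k)
  })
  do.call(rbind, tabs)
}
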