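#' Task configuration for the intrasaccadic displacement task
#'
#' Encodes the geometry and timing of the STEP/BLANK displacement task: the
#' fixation cross appears 6 or 8 degrees left or right of screen centre, the
#' saccade target at 6 or 8 degrees on the opposite side (stimulus amplitudes
#' of 12, 14 or 16 degrees), and the intrasaccadic target displacement is
#' driven by three interleaved one-up-one-down staircases. In the BLANK
#' condition the target is extinguished for 250 ms after saccade onset before
#' reappearing displaced; in STEP it reappears immediately.
#'
#' @param condition `"STEP"` or `"BLANK"`.
#' @param direction Saccade direction, `"leftward"` or `"rightward"` (fixed
#'   within a block run).
#' @param blocks Number of 24-trial blocks per direction (5 or 6).
#' @param fixation_eccentricities,target_eccentricities Allowed eccentricities
#'   in degrees (defaults `c(6, 8)`).
#' @param foreperiod_range Fixation foreperiod range in ms.
#' @param response_window_ms Maximum response time in ms.
#' @return An object of class `task_config`.
#' @export
task_config <- function(condition = c("STEP", "BLANK"),
                        direction = c("rightward", "leftward"),
                        blocks = 5,
                        fixation_eccentricities = c(6, 8),
                        target_eccentricities = c(6, 8),
                        foreperiod_range = c(1600, 2400),
                        response_window_ms = 5000) {
  condition <- match.arg(condition)
  direction <- match.arg(direction)
  if (!blocks %in% c(5L, 6L)) {
    stop("blocks per condition must be 5 or 6", call. = FALSE)
  }
  step_size <- if (condition == "STEP") 3.0 else 1.5
  starts <- if (condition == "STEP") c(-7, 0, 7) else c(-3.5, 0, 3.5)
  amps <- sort(unique(outer(fixation_eccentricities,
                            target_eccentricities, `+`)))
  if (!all(amps %in% c(12, 14, 16))) {
    stop("stimulus amplitudes must lie in {12, 14, 16} degrees", call. = FALSE)
  }
  structure(
    list(condition = condition,
         direction = direction,
         blocks = as.integer(blocks),
         trials_per_block = 24L,
         fixation_eccentricities = fixation_eccentricities,
         target_eccentricities = target_eccentricities,
         foreperiod_range = foreperiod_range,
         response_window_ms = response_window_ms,
         blank_duration_ms = if (condition == "BLANK") 250 else 0,
         step_size = step_size,
         staircase_starts = starts),
    class = "task_config")
}

#' Initialise a one-up-one-down staircase
#'
#' @param start Starting displacement level in degrees, forward-positive
#'   relative to saccade direction.
#' @param step_size Constant step size in degrees (3 in STEP, 1.5 in BLANK).
#' @param id Staircase identifier (1, 2 or 3).
#' @return An object of class `staircase`.
#' @export
staircase <- function(start, step_size, id = 1L) {
  if (step_size <= 0) stop("step_size must be positive", call. = FALSE)
  structure(
    list(id = as.integer(id),
         start = start,
         step_size = step_size,
         level = start,
         history = data.frame(level = numeric(0),
                              report = character(0),
                              stringsAsFactors = FALSE)),
    class = "staircase")
}

#' Update a staircase from a perceptual report
#'
#' One-up-one-down logic in forward-positive coordinates: a "forward" report
#' (jump seen in saccade direction) lowers the next level by one step; a
#' "backward" report raises it. A void trial (`report = "none"`, no key press
#' within the response window) leaves the level unchanged but is appended to
#' the history so the level can be re-presented later.
#'
#' @param state A `staircase` object.
#' @param report `"forward"`, `"backward"` or `"none"`.
#' @return The updated `staircase`.
#' @export
staircase_update <- function(state, report) {
  stopifnot(inherits(state, "staircase"))
  if (!report %in% c("forward", "backward", "none")) {
    stop("report must be 'forward', 'backward' or 'none'", call. = FALSE)
  }
  state$history <- rbind(state$history,
                         data.frame(level = state$level, report = report,
                                    stringsAsFactors = FALSE))
  if (report == "forward") {
    state$level <- state$level - state$step_size
  } else if (report == "backward") {
    state$level <- state$level + state$step_size
  }
  state
}

#' Displacement lattice sampled by a set of interleaved staircases
#'
#' Returns the union of the arithmetic lattices reachable by staircases with
#' the given starting levels and common step size, restricted to a window, and
#' the resulting sampling resolution (minimal spacing between distinct union
#' levels). The standard designs give a 1 degree resolution for STEP (starts
#' -7/0/+7, step 3) and 0.5 degrees for BLANK (starts -3.5/0/+3.5, step 1.5).
#'
#' @param starts Staircase starting levels in degrees.
#' @param step_size Common step size in degrees (> 0).
#' @param window Half-width in degrees of the reporting window (default 10).
#' @return A list with `levels` (sorted union) and `resolution` (degrees).
#' @export
staircase_lattice <- function(starts, step_size, window = 10) {
  if (length(starts) == 0) stop("starts must be non-empty", call. = FALSE)
  if (!is.numeric(step_size) || length(step_size) != 1 || step_size <= 0) {
    stop("step_size must be a positive scalar", call. = FALSE)
  }
  levels <- sort(unique(unlist(lapply(starts, function(s) {
    k <- seq(ceiling((-window - s) / step_size),
             floor((window - s) / step_size))
    s + k * step_size
  }))))
  resolution <- if (length(levels) > 1) min(diff(levels)) else step_size
  list(levels = levels, resolution = resolution)
}

#' Schedule a session of the displacement task
#'
#' Emits the trial skeletons for one condition and direction: `blocks` x 24
#' trials, each drawing fixation and target eccentricity independently and
#' uniformly from their sets, a foreperiod uniform over its range, and a
#' seeded random interleave of the three staircases with near-equal counts
#' (within one trial of each other).
#'
#' @param config A `task_config`.
#' @param seed Integer seed for the schedule randomisation.
#' @return A data frame of trial skeletons with screen-coordinate fixation and
#'   target positions (rightward-positive degrees) and signed stimulus
#'   amplitude.
#' @export
schedule_session <- function(config, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n <- config$blocks * config$trials_per_block
  rng <- new_rng(seed)
  # balanced staircase assignment: as equal as 3 staircases allow, permuted
  sc <- rep_len(1:3, n)
  sc <- sc[rng$sample_int(n)]
  fix_ecc <- config$fixation_eccentricities[
    rng$sample_int(length(config$fixation_eccentricities), n, replace = TRUE)]
  tar_ecc <- config$target_eccentricities[
    rng$sample_int(length(config$target_eccentricities), n, replace = TRUE)]
  foreperiod <- rng$runif(n, config$foreperiod_range[1],
                          config$foreperiod_range[2])
  sgn <- if (config$direction == "rightward") 1 else -1
  fixation <- -sgn * fix_ecc      # fixation on the opposite side of the target
  target <- sgn * tar_ecc
  data.frame(
    trial_index = seq_len(n),
    block = rep(seq_len(config$blocks), each = config$trials_per_block),
    condition = config$condition,
    direction = config$direction,
    fixation_position = fixation,
    target_position = target,
    stimulus_amplitude = target - fixation,
    foreperiod_ms = foreperiod,
    staircase_id = sc,
    stringsAsFactors = FALSE)
}

#' Create a private random-number stream
#'
#' Returns a small closure-based generator whose draws are reproducible from
#' `seed` and never touch the caller's `.Random.seed`. Used throughout the
#' simulators so that schedules and sessions are deterministic per seed.
#'
#' @param seed Integer seed for the stream.
#' @return A list with functions `runif(n)`, `rnorm(n, mean, sd)`,
#'   `sample_int(n, size, replace)` and `rbinom(n, size, prob)`.
#' @export
new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      f(...)
    }
  }
  env$runif <- with_state(stats::runif)
  env$rnorm <- with_state(stats::rnorm)
  env$sample_int <- with_state(function(n, size = n, replace = FALSE)
    sample.int(n, size, replace = replace))
  env$rbinom <- with_state(stats::rbinom)
  env
}
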