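#' Synthesise a 500 Hz eye-position trace for one trial
#'
#' Builds a horizontal gaze trace consisting of a pre-saccadic fixation
#' (>= 200 ms), a saccade with a raised-cosine velocity profile, and a
#' post-saccadic fixation (>= 250 ms), plus additive Gaussian position noise.
#' Saccade duration follows a standard main-sequence rule
#' `T = 2.2 * amplitude + 21` ms, so a 14 degree saccade lasts about 52 ms
#' and its peak velocity (2 * amplitude / T) far exceeds the 30 deg/s
#' detection criterion.
#'
#' Two kinds of ground truth are returned: the movement onset/offset (the
#' start and end of the velocity pulse; the position change between them
#' equals the executed amplitude exactly) and the analytic times at which the
#' velocity profile crosses 30 deg/s, which is what a velocity-criterion
#' detector can recover. A simulated display-trigger time (threshold crossing
#' plus one 110 Hz frame) is included.
#'
#' @param amplitude Signed saccade amplitude in screen degrees (non-zero).
#' @param start_position Pre-saccadic gaze position, degrees.
#' @param sampling_rate Samples per second (default 500).
#' @param noise_sd SD of additive position noise, degrees.
#' @param rng A private RNG stream from `new_rng()`; required if
#'   `noise_sd > 0`.
#' @param pre_ms,post_ms Fixation durations before and after the saccade.
#' @return A list with `trace` (data frame `time_ms`, `x_deg`) and `truth`
#'   (movement onset/offset ms, threshold-crossing times at 30 deg/s,
#'   peak velocity, trigger time).
#' @export
generate_eye_trace <- function(amplitude, start_position = 0,
                               sampling_rate = 500, noise_sd = 0,
                               rng = NULL, pre_ms = 300, post_ms = 300) {
  stopifnot(abs(amplitude) > 0, noise_sd >= 0, pre_ms >= 200, post_ms >= 250)
  A <- abs(amplitude)
  dur_ms <- 2.2 * A + 21
  dt <- 1000 / sampling_rate
  t <- seq(0, pre_ms + dur_ms + post_ms, by = dt)
  onset <- pre_ms
  offset <- pre_ms + dur_ms
  # raised-cosine velocity: v(u) = vp/2 * (1 - cos(2*pi*u/T)), u in [0, T]
  # position is its integral: x(u) = A * (u/T - sin(2*pi*u/T) / (2*pi))
  u <- pmin(pmax(t - onset, 0), dur_ms)
  x <- start_position + sign(amplitude) * A *
    (u / dur_ms - sin(2 * pi * u / dur_ms) / (2 * pi))
  if (noise_sd > 0) {
    if (is.null(rng)) stop("rng required when noise_sd > 0", call. = FALSE)
    x <- x + rng$rnorm(length(x), 0, noise_sd)
  }
  vp <- 2 * A / (dur_ms / 1000)            # peak velocity, deg/s
  # time after movement onset at which |v| crosses 30 deg/s
  thr <- 30
  u30 <- if (vp > thr) {
    dur_ms / (2 * pi) * acos(1 - 2 * thr / vp)
  } else NA_real_
  structure(list(
    trace = data.frame(time_ms = t, x_deg = x),
    truth = list(movement_onset_ms = onset,
                 movement_offset_ms = offset,
                 thr_onset_ms = onset + u30,
                 thr_offset_ms = offset - u30,
                 duration_ms = dur_ms,
                 peak_velocity = vp,
                 trigger_ms = onset + u30 + 1000 / 110,
                 amplitude = amplitude,
                 sampling_rate = sampling_rate)),
    class = "eye_trace")
}
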