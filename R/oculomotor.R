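#' Zero-phase low-pass filter an eye trace and compute velocity
#'
#' Applies a zero-phase second-order Butterworth low-pass filter
#' (`signal::filtfilt`) to the position samples and computes velocity by
#' central differences on the filtered positions.
#'
#' @param trace Data frame with columns `time_ms` and `x_deg`, uniformly
#'   sampled.
#' @param cutoff_hz Low-pass cutoff frequency (default 60 Hz).
#' @return The trace with filtered `x_deg` and a `v_degs` velocity column
#'   (deg/s).
#' @export
filter_trace <- function(trace, cutoff_hz = 60) {
  stopifnot(all(c("time_ms", "x_deg") %in% names(trace)))
  n <- nrow(trace)
  if (n < 13) stop("trace shorter than filter span", call. = FALSE)
  dt <- diff(trace$time_ms[1:2]) / 1000
  fs <- 1 / dt
  bf <- signal::butter(2, cutoff_hz / (fs / 2), type = "low")
  # odd-reflection padding keeps the filter's start-up transient out of the
  # trace (filtfilt assumes zero initial conditions)
  np <- min(n - 1, 50)
  x0 <- trace$x_deg
  padded <- c(2 * x0[1] - x0[(np + 1):2], x0, 2 * x0[n] - x0[(n - 1):(n - np)])
  xf <- as.numeric(signal::filtfilt(bf, padded))
  x <- xf[(np + 1):(np + n)]
  v <- rep(NA_real_, n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  v[1] <- v[2]; v[n] <- v[n - 1]
  data.frame(time_ms = trace$time_ms, x_deg = x, v_degs = v)
}

#' Detect the principal saccade in a filtered trace
#'
#' Applies a fixed velocity criterion: samples with |velocity| > 30 deg/s are
#' suprathreshold; contiguous runs are candidate saccades, the one with the
#' largest position change is the principal event. Onset is the first
#' suprathreshold sample of that run and offset the first subsequent sample
#' below threshold. Start and end positions are medians of fixation windows
#' (default 50 ms) before onset and after offset. A trial containing more
#' than one candidate run (e.g. a corrective saccade) is flagged.
#'
#' @param ftrace Output of `filter_trace()`.
#' @param threshold Velocity criterion in deg/s (default 30).
#' @param fixation_ms Fixation-window length for start/end positions.
#' @param min_duration_ms Minimum run duration to count as a candidate.
#' @return A list of class `saccade_event` with onset/offset times,
#'   start/end positions, amplitude, duration, peak velocity and a
#'   `multiple` flag.
#' @export
detect_saccade <- function(ftrace, threshold = 30, fixation_ms = 50,
                           min_duration_ms = 6) {
  stopifnot(all(c("time_ms", "x_deg", "v_degs") %in% names(ftrace)))
  supra <- abs(ftrace$v_degs) > threshold
  if (!any(supra)) stop("no saccade: velocity never exceeds threshold",
                        call. = FALSE)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  dt <- diff(ftrace$time_ms[1:2])
  keep <- r$values & r$lengths * dt >= min_duration_ms
  if (!any(keep)) stop("no saccade: velocity never exceeds threshold",
                       call. = FALSE)
  runs <- data.frame(start = starts[keep], end = ends[keep])
  runs$amp <- abs(ftrace$x_deg[pmin(runs$end + 1, nrow(ftrace))] -
                  ftrace$x_deg[pmax(runs$start - 1, 1)])
  k <- which.max(runs$amp)
  onset_i <- runs$start[k]
  offset_i <- min(runs$end[k] + 1, nrow(ftrace))
  onset <- ftrace$time_ms[onset_i]
  offset <- ftrace$time_ms[offset_i]
  pre <- ftrace$time_ms < onset & ftrace$time_ms >= onset - fixation_ms
  post <- ftrace$time_ms > offset & ftrace$time_ms <= offset + fixation_ms
  start_pos <- stats::median(ftrace$x_deg[pre])
  end_pos <- stats::median(ftrace$x_deg[post])
  structure(list(onset_ms = onset, offset_ms = offset,
                 start_position = start_pos, end_position = end_pos,
                 amplitude = end_pos - start_pos,
                 duration_ms = offset - onset,
                 peak_velocity = max(abs(ftrace$v_degs[onset_i:offset_i])),
                 multiple = nrow(runs) > 1),
            class = "saccade_event")
}

#' Targeting metrics per condition and direction
#'
#' Computes, per trial, the amplitude gain (saccade amplitude divided by
#' stimulus amplitude) and the signed targeting error
#' `|landing - fixation| - |stimulus amplitude|` — negative when the saccade
#' lands short of the target (undershoot). The sign-flipped
#' `hypometria_error` (positive = hypometric) is the convention used for
#' error-attribution binning. Aggregates mean gain, mean targeting error and
#' its SD (the variable error) per condition x direction cell.
#'
#' @param trials Trial table with columns `condition`, `direction`,
#'   `fixation_position`, `target_position`, `stimulus_amplitude`,
#'   `saccade_landing` (NA allowed for missing landings).
#' @return A list with `trials` (per-trial metrics appended) and `summary`
#'   (one row per condition x direction, with the count of excluded trials).
#' @export
targeting_metrics <- function(trials) {
  need <- c("condition", "direction", "fixation_position",
            "target_position", "stimulus_amplitude", "saccade_landing")
  stopifnot(all(need %in% names(trials)))
  amp <- abs(trials$saccade_landing - trials$fixation_position)
  trials$gain <- amp / abs(trials$stimulus_amplitude)
  trials$targeting_error <- amp - abs(trials$stimulus_amplitude)
  trials$hypometria_error <- -trials$targeting_error
  ok <- !is.na(trials$saccade_landing)
  # saccades opposite to the instructed direction are excluded and counted
  sgn <- ifelse(trials$direction == "rightward", 1, -1)
  wrong_way <- ok & sign(trials$saccade_landing - trials$fixation_position) != sgn
  use <- ok & !wrong_way
  cells <- unique(trials[c("condition", "direction")])
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- use & trials$condition == cells$condition[k] &
      trials$direction == cells$direction[k]
    all_in_cell <- trials$condition == cells$condition[k] &
      trials$direction == cells$direction[k]
    data.frame(condition = cells$condition[k],
               direction = cells$direction[k],
               n = sum(sel),
               n_excluded = sum(all_in_cell) - sum(sel),
               gain = mean(trials$gain[sel]),
               targeting_error = mean(trials$targeting_error[sel]),
               variable_error = stats::sd(trials$targeting_error[sel]),
               stringsAsFactors = FALSE)
  }))
  trials$included <- use
  list(trials = trials, summary = summ)
}

#' Check gaze-contingent trigger timing against saccade midpoints
#'
#' @param events List of `saccade_event`s (or data frame with `onset_ms`,
#'   `offset_ms`).
#' @param trigger_times Per-trial trigger timestamps (ms, same clock as the
#'   events).
#' @return A list with the fraction of triggers before the saccade midpoint,
#'   mean and SD of the delay after onset, and the indices of flagged trials
#'   (trigger at or after midpoint).
#' @export
trigger_check <- function(events, trigger_times) {
  if (is.data.frame(events)) {
    onset <- events$onset_ms; offset <- events$offset_ms
  } else {
    onset <- vapply(events, `[[`, numeric(1), "onset_ms")
    offset <- vapply(events, `[[`, numeric(1), "offset_ms")
  }
  stopifnot(length(trigger_times) == length(onset))
  mid <- (onset + offset) / 2
  delay <- trigger_times - onset
  before_mid <- trigger_times < mid
  list(fraction_before_midpoint = mean(before_mid),
       delay_mean_ms = mean(delay),
       delay_sd_ms = stats::sd(delay),
       flagged = which(!before_mid))
}
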