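#' Write / read a trial table
#'
#' Trial tables are comma-separated text with a header row and one row per
#' trial; missing values are written as empty fields. Column names follow
#' the simulator's output (`trial_index`, `block`, `condition`, `direction`,
#' `fixation_position`, `target_position`, `stimulus_amplitude`,
#' `foreperiod_ms`, `staircase_id`, `displacement`, `report`,
#' `saccade_landing`, `motor_error`, `trigger_delay_ms`).
#'
#' @param trials A trial-table data frame.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an eye trace in long delimited format
#'
#' Columns `trial_index`, `time_ms`, `x_deg`.
#'
#' @param traces Data frame in long format.
#' @param path Output CSV path.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Patient demographic and lesion characteristics table
#'
#' The cohort description shipped with the package: age (years), sex,
#' education (years), premorbid IQ estimate, time since lesion (months),
#' lesion side (R/L unilateral, B_R/B_L bilateral with right/left
#' predominance) and lesion volume (cm^3) for the 14 thalamic-stroke
#' patients. Values transcribed from the published cohort table.
#'
#' @return A data frame with one row per patient.
#' @export
patient_table <- function() {
  path <- system.file("extdata", "table1_patients.csv", package = "sacdisp")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Descriptive statistics of the patient cohort table
#'
#' Means (and the sample SD of age) of the numeric cohort characteristics,
#' plus the percentage of unilateral-right lesions.
#'
#' @param tab A patient table as from `patient_table()`.
#' @return A named list of summary statistics.
#' @export
patient_table_summary <- function(tab = patient_table()) {
  list(n = nrow(tab),
       mean_age = mean(tab$age),
       sd_age = stats::sd(tab$age),
       mean_tsl_months = mean(tab$tsl_months),
       mean_lesion_volume_cm3 = mean(tab$lesion_volume_cm3),
       pct_unilateral_right = 100 * mean(tab$lesion_side == "R"),
       pct_unilateral_left = 100 * mean(tab$lesion_side == "L"),
       pct_bilateral = 100 * mean(tab$lesion_side %in% c("B_R", "B_L")))
}

#' Synthetic thalamic atlas on a cohort grid
#'
#' A toy nucleus parcellation for exercising atlas-label association: label
#' 1 ("MD") is a block containing the planted critical region, label 2
#' ("CL") a thin adjacent shell, label 3 ("VL") a lateral block and label 4
#' ("Pul") a posterior block. Synthetic: the geometry is illustrative, not a
#' tracing of any real atlas.
#'
#' @param spec A `lesion_cohort_spec`.
#' @return A list with `atlas` (integer 3D array) and `names`.
#' @export
synthetic_atlas <- function(spec) {
  shape <- spec$grid_shape
  atlas <- array(0L, shape)
  ctr <- round((spec$critical_centre_mm - spec$origin_mm) /
                 spec$voxel_size_mm + 1)
  block <- function(centre, half) {
    rng <- lapply(1:3, function(a)
      max(1, centre[a] - half[a]):min(shape[a], centre[a] + half[a]))
    as.matrix(expand.grid(rng))
  }
  atlas[block(ctr, c(3, 3, 3))] <- 1L
  shell <- block(ctr, c(5, 5, 5))
  inner <- block(ctr, c(3, 3, 3))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  shell <- shell[!key(shell) %in% key(inner), , drop = FALSE]
  atlas[shell] <- 2L
  atlas[block(ctr + c(7, 0, 0), c(2, 3, 3))] <- 3L
  atlas[block(ctr + c(0, -8, 0), c(3, 2, 3))] <- 4L
  list(atlas = atlas,
       names = c(`1` = "MD", `2` = "CL", `3` = "VL", `4` = "Pul"))
}
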