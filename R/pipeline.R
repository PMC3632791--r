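#' Configuration for the end-to-end synthetic pipeline
#'
#' Ties together the task design, the cohort composition (controls plus
#' lesion patients whose behavioural phenotype is driven by whether their
#' synthetic lesion hits the planted critical region), the per-stage seeds
#' and the output directory.
#'
#' @param n_controls Number of control observers.
#' @param lesion_spec A `lesion_cohort_spec` defining the patient cohort.
#' @param blocks Blocks per condition and direction.
#' @param n_trace_trials Trials per subject for which full eye traces are
#'   synthesised and run through saccade detection.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param output_dir Where `run_pipeline()` writes its artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_controls = 8,
                            lesion_spec = lesion_cohort_spec(n_patients = 10),
                            blocks = 5,
                            n_trace_trials = 20,
                            seed = 1L,
                            output_dir = tempfile("sacdisp_run_")) {
  structure(list(n_controls = n_controls,
                 lesion_spec = lesion_spec,
                 blocks = blocks,
                 n_trace_trials = n_trace_trials,
                 seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # FNV-1a over the deparsed configuration; enough to fingerprint a run
  s <- paste(deparse(config), collapse = "\n")
  xor32 <- function(a, b) {   # 32-bit XOR on doubles via 16-bit halves
    hi <- bitwXor(a %/% 65536, b %/% 65536)
    lo <- bitwXor(a %% 65536, b %% 65536)
    hi * 65536 + lo
  }
  mul32 <- function(a, p) {   # (a * p) mod 2^32 without losing precision
    (((a %/% 65536 * p) %% 65536) * 65536 + (a %% 65536) * p) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- mul32(xor32(h, b), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full synthetic analysis pipeline
#'
#' Stages: (1) simulate a lesion cohort and the behavioural sessions of all
#' subjects — patients whose lesion overlaps the planted critical region get
#' a lesion-like observer (hypometric, uncoupled corollary discharge) for
#' one saccade direction; (2) synthesise and detect eye traces for a subset
#' of trials and check the gaze-contingent trigger timing; (3) fit
#' psychometric functions per condition and direction; (4) build deficit
#' profiles and classify subjects against the control norms; (5) run
#' voxel-based lesion-symptom mapping on the patients using the
#' asymmetry-impairment flag derived from behaviour. Every stage writes its
#' tables (and NIfTI maps) under `config$output_dir` together with a run
#' manifest recording seeds, configuration hash and per-stage counts.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list bundle with all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf(...))
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   r_version = as.character(getRversion()),
                   stages = list())

  # --- stage 1: simulate -------------------------------------------------
  cohort <- generate_lesion_cohort(config$lesion_spec,
                                   seed = config$seed + 11L)
  write_lesion_cohort(cohort, file.path(config$output_dir, "lesions"))
  n_pat <- config$lesion_spec$n_patients
  subjects <- c(sprintf("C%02d", seq_len(config$n_controls)),
                cohort$patient_ids)
  is_control <- c(rep(TRUE, config$n_controls), rep(FALSE, n_pat))
  rng <- new_rng(config$seed + 23L)
  affected_dir <- ifelse(rng$runif(n_pat) < 0.5, "leftward", "rightward")
  trials <- list()
  for (s in seq_along(subjects)) {
    if (is_control[s]) {
      params <- observer_preset("control")
    } else {
      p_idx <- s - config$n_controls
      if (cohort$true_overlap[p_idx]) {
        params <- list(leftward = observer_preset("control"),
                       rightward = observer_preset("control"))
        params[[affected_dir[p_idx]]] <- observer_preset("thalamic")
      } else {
        params <- observer_preset("control")
      }
    }
    tab <- simulate_subject(params, seed = config$seed * 100L + s,
                            blocks = config$blocks)
    tab$subject <- subjects[s]
    trials[[s]] <- tab
  }
  all_trials <- do.call(rbind, trials)
  write_trials(all_trials, file.path(config$output_dir, "trials.csv"))
  manifest$stages$simulate <- list(n_subjects = length(subjects),
                                   n_trials = nrow(all_trials))
  log_stage("simulate: %d subjects, %d trials", length(subjects),
            nrow(all_trials))

  # --- stage 2: oculomotor traces ---------------------------------------
  trng <- new_rng(config$seed + 31L)
  take <- all_trials[seq_len(min(config$n_trace_trials * length(subjects),
                                 nrow(all_trials))), ]
  detect_rows <- lapply(seq_len(nrow(take)), function(i) {
    amp <- take$saccade_landing[i] - take$fixation_position[i]
    tr <- generate_eye_trace(amp, take$fixation_position[i],
                             noise_sd = 0.05, rng = trng)
    ev <- detect_saccade(filter_trace(tr$trace))
    data.frame(onset_ms = ev$onset_ms, offset_ms = ev$offset_ms,
               amplitude = ev$amplitude, true_amplitude = amp,
               trigger_ms = tr$truth$trigger_ms)
  })
  events <- do.call(rbind, detect_rows)
  trig <- trigger_check(events[c("onset_ms", "offset_ms")],
                        events$trigger_ms)
  utils::write.csv(events, file.path(config$output_dir, "saccade_events.csv"),
                   row.names = FALSE)
  manifest$stages$oculomotor <- list(
    n_traces = nrow(events),
    amplitude_rmse = sqrt(mean((events$amplitude - events$true_amplitude)^2)),
    trigger_before_midpoint = trig$fraction_before_midpoint)
  log_stage("oculomotor: %d traces, trigger-before-midpoint %.2f",
            nrow(events), trig$fraction_before_midpoint)

  # --- stage 3: fit ------------------------------------------------------
  fits <- do.call(rbind, lapply(split(all_trials, all_trials$subject),
                                function(tt) {
    f <- fit_subject(tt)
    f$subject <- tt$subject[1]
    f
  }))
  utils::write.csv(fits, file.path(config$output_dir, "fits.csv"),
                   row.names = FALSE)
  manifest$stages$fit <- list(n_fits = nrow(fits))
  log_stage("fit: %d psychometric fits", nrow(fits))

  # --- stage 4: profiles -------------------------------------------------
  scores <- do.call(rbind, lapply(split(all_trials, all_trials$subject),
                                  function(tt) {
    sc <- subject_scores(fits[fits$subject == tt$subject[1], ], tt)
    sc$subject <- tt$subject[1]
    sc
  }))
  prof <- cohort_profiles(scores, control_ids = subjects[is_control])
  utils::write.csv(prof$profiles,
                   file.path(config$output_dir, "profiles.csv"),
                   row.names = FALSE)
  manifest$stages$profile <- list(
    n_impaired_asymmetry = sum(prof$profiles$impaired_asymmetry))
  log_stage("profile: %d subjects flagged on asymmetry",
            sum(prof$profiles$impaired_asymmetry))

  # --- stage 5: vlsm -----------------------------------------------------
  pat_prof <- prof$profiles[match(cohort$patient_ids,
                                  prof$profiles$subject), ]
  behav_cohort <- cohort
  behav_cohort$impaired <- pat_prof$impaired_asymmetry |
    pat_prof$impaired_rel_left | pat_prof$impaired_rel_right
  vl <- NULL
  if (any(behav_cohort$impaired) && !all(behav_cohort$impaired)) {
    vl <- vlsm_map(behav_cohort)
    write_map_nifti(vl$z_map, behav_cohort,
                    file.path(config$output_dir, "vlsm_z.nii.gz"))
    sub <- subtraction_map(behav_cohort)
    write_map_nifti(sub, behav_cohort,
                    file.path(config$output_dir, "subtraction.nii.gz"))
    pw <- power_map(behav_cohort)
    write_map_nifti(pw$powered_mask, behav_cohort,
                    file.path(config$output_dir, "power.nii.gz"))
    manifest$stages$vlsm <- list(n_included = vl$n_included,
                                 peak_mm = if (!is.null(vl$peak)) vl$peak$mm)
    log_stage("vlsm: %d voxels tested", vl$n_included)
  } else {
    manifest$stages$vlsm <- list(skipped = "behavioural labels degenerate")
    log_stage("vlsm: skipped (labels all equal)")
  }

  bundle <- list(config = config, manifest = manifest, cohort = cohort,
                 trials = all_trials, events = events, trigger = trig,
                 fits = fits, profiles = prof, vlsm = vl)
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("config_hash: %s", manifest$config_hash),
               sprintf("r_version: %s", manifest$r_version),
               utils::capture.output(utils::str(manifest$stages))),
             file.path(config$output_dir, "manifest.txt"))
  invisible(bundle)
}

#' Summarise a pipeline bundle into a cohort report
#'
#' Writes (and returns) the cohort-style summaries: demographic descriptives
#' of the shipped patient table, group mean thresholds per condition and
#' direction, the per-subject impairment flags, the error-attribution
#' correlations, and the VLSM peak.
#'
#' @param bundle Result of `run_pipeline()`.
#' @param dir Output directory (defaults to the bundle's).
#' @return A list of report tables.
#' @export
make_report <- function(bundle, dir = bundle$config$output_dir) {
  if (is.null(bundle$fits) || nrow(bundle$fits) == 0) {
    stop("empty cohort: nothing to report", call. = FALSE)
  }
  demo <- patient_table_summary()
  thr <- stats::aggregate(threshold ~ condition + direction,
                          data = bundle$fits, FUN = mean)
  flags <- bundle$profiles$profiles[
    c("subject", "is_control", "impaired_rel_left", "impaired_rel_right",
      "impaired_asymmetry", "impaired_attr_left", "impaired_attr_right")]
  peak <- if (!is.null(bundle$vlsm) && !is.null(bundle$vlsm$peak)) {
    data.frame(x_mm = bundle$vlsm$peak$mm[1], y_mm = bundle$vlsm$peak$mm[2],
               z_mm = bundle$vlsm$peak$mm[3], z_score = bundle$vlsm$peak$z,
               p = bundle$vlsm$peak$p)
  } else data.frame()
  utils::write.csv(thr, file.path(dir, "report_thresholds.csv"),
                   row.names = FALSE)
  utils::write.csv(flags, file.path(dir, "report_flags.csv"),
                   row.names = FALSE)
  if (nrow(peak)) {
    utils::write.csv(peak, file.path(dir, "report_vlsm_peak.csv"),
                     row.names = FALSE)
  }
  writeLines(c(
    sprintf("Cohort report (seed %d, config %s)", bundle$config$seed,
            bundle$manifest$config_hash),
    sprintf("Patient table: n=%d, mean age %.1f y (SD %.1f), mean TSL %.1f mo,",
            demo$n, demo$mean_age, demo$sd_age, demo$mean_tsl_months),
    sprintf("  mean lesion volume %.2f cm3, %.0f%% unilateral right",
            demo$mean_lesion_volume_cm3, demo$pct_unilateral_right),
    sprintf("Group mean thresholds:"),
    utils::capture.output(print(thr)),
    sprintf("Impaired on asymmetry: %d / %d subjects",
            sum(flags$impaired_asymmetry), nrow(flags)),
    if (nrow(peak)) sprintf("VLSM peak at mm [%g, %g, %g], z = %.2f",
                            peak$x_mm, peak$y_mm, peak$z_mm, peak$z_score)
    else "VLSM stage skipped"),
    file.path(dir, "report.txt"))
  list(demographics = demo, thresholds = thr, flags = flags, vlsm_peak = peak)
}
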