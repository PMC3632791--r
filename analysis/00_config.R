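# Shared configuration for the numbered analysis drivers.
# Source this from each driver; it defines the master seed, the cohort
# composition and the output locations so every stage agrees on them.

suppressPackageStartupMessages(library(sacdisp))

SEED <- 20130L                     # master seed for the whole analysis
RESULTS <- "results"               # all stage outputs land here
BLOCKS <- 6                        # staircase blocks per condition/direction

N_CONTROLS <- 8
CONTROL_IDS <- sprintf("C%02d", seq_len(N_CONTROLS))
LESION_SPEC <- lesion_cohort_spec()          # 14 patients, 32 mm^3 grid

dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

paths <- list(
  lesion_dir   = file.path(RESULTS, "lesions"),
  trials       = file.path(RESULTS, "trials.csv"),
  affected     = file.path(RESULTS, "affected_directions.csv"),
  events       = file.path(RESULTS, "saccade_events.csv"),
  ocu_summary  = file.path(RESULTS, "oculomotor_summary.csv"),
  fits         = file.path(RESULTS, "fits.csv"),
  profiles     = file.path(RESULTS, "profiles.csv"),
  norms        = file.path(RESULTS, "control_norms.csv"),
  vlsm_z       = file.path(RESULTS, "vlsm_z.nii.gz"),
  subtraction  = file.path(RESULTS, "subtraction.nii.gz"),
  power        = file.path(RESULTS, "power.nii.gz"),
  vlsm_peak    = file.path(RESULTS, "vlsm_peak.csv"),
  atlas_assoc  = file.path(RESULTS, "atlas_association.csv"),
  report       = file.path(RESULTS, "report.txt")
)
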