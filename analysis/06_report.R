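# Stage 6 — cohort report.
#
# Collates the previous stages into a short plain-text report: demographic
# descriptives of the shipped patient table, group mean thresholds per
# condition and direction, the impairment flags, the oculomotor validation
# summary and the lesion-mapping peak.

# Run from the repository root: Rscript analysis/06_report.R
source("analysis/00_config.R")

demo <- patient_table_summary()
fits <- read.csv(paths$fits, stringsAsFactors = FALSE)
prof <- read.csv(paths$profiles, stringsAsFactors = FALSE)
ocu <- read.csv(paths$ocu_summary, stringsAsFactors = FALSE)
peak <- if (file.exists(paths$vlsm_peak))
  read.csv(paths$vlsm_peak) else NULL

thr <- aggregate(threshold ~ condition + direction, data = fits, FUN = mean)
flagged <- prof$subject[prof$impaired_asymmetry | prof$impaired_rel_left |
                        prof$impaired_rel_right]

lines <- c(
  sprintf("Trans-saccadic displacement cohort report (seed %d)", SEED),
  "",
  sprintf("Patient table: n = %d, mean age %.1f y (SD %.1f),", demo$n,
          demo$mean_age, demo$sd_age),
  sprintf("  mean time since lesion %.1f months, mean lesion volume %.2f cm3,",
          demo$mean_tsl_months, demo$mean_lesion_volume_cm3),
  sprintf("  %.0f%% unilateral right lesions", demo$pct_unilateral_right),
  "",
  "Group mean 75%-correct thresholds (deg):",
  capture.output(print(thr, row.names = FALSE)),
  "",
  sprintf("Impaired subjects (any 1.96 SD flag): %s",
          if (length(flagged)) paste(flagged, collapse = ", ") else "none"),
  "",
  sprintf("Oculomotor check: %d traces, amplitude RMSE %.3f deg,",
          ocu$n_traces, ocu$amplitude_rmse_deg),
  sprintf("  trigger before saccade midpoint in %.0f%% of trials",
          100 * ocu$trigger_before_midpoint),
  "",
  if (!is.null(peak))
    sprintf("VLSM peak: z = %.2f (p = %.3g) at [%g, %g, %g] mm",
            peak$z_score, peak$p, peak$x_mm, peak$y_mm, peak$z_mm)
  else "VLSM stage not run")
writeLines(lines, paths$report)
writeLines(lines)
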