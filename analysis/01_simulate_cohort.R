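# Stage 1 — simulate the study cohort.
#
# Generates a synthetic lesion cohort with a planted critical region, then
# simulates the full behavioural experiment (STEP and BLANK staircases, both
# saccade directions) for the controls and for every patient. Patients whose
# lesion truly overlaps the critical region get a lesion-like observer
# (hypometric, uncoupled corollary discharge) for one randomly chosen saccade
# direction; everyone else behaves like a control.

# Run from the repository root: Rscript analysis/01_simulate_cohort.R
source("analysis/00_config.R")

cohort <- generate_lesion_cohort(LESION_SPEC, seed = SEED + 11L)
write_lesion_cohort(cohort, paths$lesion_dir)
message(sprintf("lesions: %d patients, %d overlapping the critical region",
                LESION_SPEC$n_patients, sum(cohort$true_overlap)))

set.seed(SEED + 23L)
affected_dir <- sample(c("leftward", "rightward"),
                       LESION_SPEC$n_patients, replace = TRUE)
write.csv(data.frame(patient_id = cohort$patient_ids,
                     true_overlap = cohort$true_overlap,
                     affected_direction = ifelse(cohort$true_overlap,
                                                 affected_dir, NA)),
          paths$affected, row.names = FALSE)

subjects <- c(CONTROL_IDS, cohort$patient_ids)
trials <- lapply(seq_along(subjects), function(s) {
  p_idx <- s - N_CONTROLS
  if (p_idx >= 1 && cohort$true_overlap[p_idx]) {
    params <- list(leftward = observer_preset("control"),
                   rightward = observer_preset("control"))
    params[[affected_dir[p_idx]]] <- observer_preset("thalamic")
  } else {
    params <- observer_preset("control")
  }
  tab <- simulate_subject(params, seed = SEED * 100L + s, blocks = BLOCKS)
  tab$subject <- subjects[s]
  tab
})
all_trials <- do.call(rbind, trials)
write_trials(all_trials, paths$trials)
message(sprintf("behaviour: %d subjects, %d trials -> %s",
                length(subjects), nrow(all_trials), paths$trials))
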