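# Stage 4 — deficit profiling.
#
# Scores every subject (relative BLANK/STEP threshold per direction,
# left-right threshold asymmetry, and the 8-bin targeting-error /
# forward-report attribution correlation), builds control norms, and flags
# subjects whose scores fall more than 1.96 control SDs from the control
# mean.

# Run from the repository root: Rscript analysis/04_deficit_profiles.R
source("analysis/00_config.R")

all_trials <- read_trials(paths$trials)
fits <- read.csv(paths$fits, stringsAsFactors = FALSE)

scores <- do.call(rbind, lapply(split(all_trials, all_trials$subject),
                                function(tt) {
  tt <- targeting_metrics(tt)$trials
  sc <- subject_scores(fits[fits$subject == tt$subject[1], ], tt)
  sc$subject <- tt$subject[1]
  sc
}))

prof <- cohort_profiles(scores, control_ids = CONTROL_IDS)
write.csv(prof$profiles, paths$profiles, row.names = FALSE)
norms <- do.call(rbind, lapply(names(prof$norms), function(nm)
  data.frame(score = nm, mean = prof$norms[[nm]]$mean,
             sd = prof$norms[[nm]]$sd, n = prof$norms[[nm]]$n)))
write.csv(norms, paths$norms, row.names = FALSE)

flagged <- prof$profiles$subject[prof$profiles$impaired_asymmetry]
message(sprintf("profiles: %d subjects, asymmetry-impaired: %s",
                nrow(prof$profiles),
                if (length(flagged)) paste(flagged, collapse = ", ")
                else "none"))
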