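# Stage 3 — psychometric fitting.
#
# Fits a maximum-likelihood cumulative Gaussian to each subject's forward /
# backward reports, separately per condition (STEP, BLANK) and saccade
# direction, and derives the point of subjective stationarity (PSS), the
# just-noticeable difference (JND) and the 75%-correct displacement
# threshold for every cell.

# Run from the repository root: Rscript analysis/03_psychometrics.R
source("analysis/00_config.R")

all_trials <- read_trials(paths$trials)
fits <- do.call(rbind, lapply(split(all_trials, all_trials$subject),
                              function(tt) {
  f <- fit_subject(tt)
  f$subject <- tt$subject[1]
  f
}))
write.csv(fits, paths$fits, row.names = FALSE)

grp <- aggregate(cbind(threshold, pss) ~ condition + direction,
                 data = fits, FUN = mean)
message("group mean thresholds / PSS:")
print(grp)
message(sprintf("%d fits -> %s", nrow(fits), paths$fits))
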