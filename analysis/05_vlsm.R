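# Stage 5 — voxel-based lesion-symptom mapping.
#
# Loads the lesion masks written in stage 1, replaces the generator's labels
# with the impairment flags derived from behaviour in stage 4, and runs the
# voxelwise Liebermeister test (voxels lesioned in at least two patients),
# the thresholded subtraction map, the best-case power map and the
# atlas-label chi-square association.

# Run from the repository root: Rscript analysis/05_vlsm.R
source("analysis/00_config.R")

labels_csv <- file.path(paths$lesion_dir, "labels.csv")
ids <- read.csv(labels_csv, stringsAsFactors = FALSE)$patient_id
cohort <- read_lesion_cohort(file.path(paths$lesion_dir,
                                       paste0(ids, ".nii.gz")), labels_csv)

prof <- read.csv(paths$profiles, stringsAsFactors = FALSE)
pp <- prof[match(cohort$patient_ids, prof$subject), ]
# The direction-specific asymmetry flag is the cleanest behavioural marker
# of a unilateral deficit; the relative-threshold flags are noisier in
# controls and would dilute the map.
cohort$impaired <- pp$impaired_asymmetry
if (!any(cohort$impaired) || all(cohort$impaired)) {
  stop("behavioural labels are degenerate; nothing to map")
}

vl <- vlsm_map(cohort, min_lesioned = 2)
write_map_nifti(vl$z_map, cohort, paths$vlsm_z)
write_map_nifti(subtraction_map(cohort), cohort, paths$subtraction)
pw <- power_map(cohort)
write_map_nifti(pw$powered_mask, cohort, paths$power)

peak <- data.frame(i = vl$peak$index[1], j = vl$peak$index[2],
                   k = vl$peak$index[3],
                   x_mm = vl$peak$mm[1], y_mm = vl$peak$mm[2],
                   z_mm = vl$peak$mm[3],
                   z_score = vl$peak$z, p = vl$peak$p)
write.csv(peak, paths$vlsm_peak, row.names = FALSE)

atl <- synthetic_atlas(LESION_SPEC)
assoc <- label_association(cohort, atl$atlas, label_names = atl$names)
write.csv(assoc, paths$atlas_assoc, row.names = FALSE)

message(sprintf(
  "vlsm: %d voxels tested; peak z = %.2f (p = %.3g) at [%g, %g, %g] mm",
  vl$n_included, peak$z_score, peak$p, peak$x_mm, peak$y_mm, peak$z_mm))
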