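#' Specification of a synthetic lesion cohort
#'
#' Describes a cohort of patients with small focal lesions on a shared voxel
#' grid, plus a planted critical region: patients whose lesion overlaps the
#' region are impaired (up to label noise). The default grid is 32^3 voxels
#' at 1 mm with an MNI-like affine placing the grid over central thalamus,
#' so the default critical region — a 2 mm-radius sphere at mm [8, -15, 4] —
#' sits in right central thalamus. Lesion centres scatter around the
#' critical-region centroid (Gaussian, SD `centre_sd` voxels), mimicking a
#' clinical cohort whose lesions cluster in one structure.
#'
#' @param grid_shape Integer vector of 3 voxel counts (default 32^3).
#' @param voxel_size_mm Isotropic voxel size (default 1 mm).
#' @param origin_mm mm coordinate of voxel (1,1,1) (default places the grid
#'   over the thalamus).
#' @param critical_centre_mm Centre of the critical region in mm.
#' @param critical_radius_mm Radius of the spherical critical region.
#' @param n_patients Cohort size (default 14).
#' @param lesion_radius_range Ellipsoid semi-axis range in voxels.
#' @param centre_sd Scatter of lesion centres around the critical centroid,
#'   voxels.
#' @param impairment_noise Probability of flipping a patient's label.
#' @return An object of class `lesion_cohort_spec`.
#' @export
lesion_cohort_spec <- function(grid_shape = c(32L, 32L, 32L),
                               voxel_size_mm = 1,
                               origin_mm = c(-16, -30, -12),
                               critical_centre_mm = c(8, -15, 4),
                               critical_radius_mm = 2,
                               n_patients = 14,
                               lesion_radius_range = c(2, 4),
                               centre_sd = 3,
                               impairment_noise = 0) {
  spec <- structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = voxel_size_mm,
         origin_mm = origin_mm,
         critical_centre_mm = critical_centre_mm,
         critical_radius_mm = critical_radius_mm,
         n_patients = as.integer(n_patients),
         lesion_radius_range = lesion_radius_range,
         centre_sd = centre_sd,
         impairment_noise = impairment_noise),
    class = "lesion_cohort_spec")
  ctr_vox <- (critical_centre_mm - origin_mm) / voxel_size_mm + 1
  if (any(ctr_vox < 1) || any(ctr_vox > grid_shape)) {
    stop("critical region lies outside the grid", call. = FALSE)
  }
  spec
}

#' mm coordinates of every voxel centre on a spec's grid
#' @param spec A `lesion_cohort_spec`.
#' @return A `grid_shape` x 3 matrix layout helper: list of three coordinate
#'   vectors (x, y, z in mm along each axis).
#' @keywords internal
grid_axes_mm <- function(spec) {
  lapply(1:3, function(a)
    spec$origin_mm[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$voxel_size_mm)
}

# logical 3D mask of an ellipsoid given centre and semi-axes (voxel units)
ellipsoid_mask <- function(shape, centre, semi_axes) {
  i <- seq_len(shape[1]); j <- seq_len(shape[2]); k <- seq_len(shape[3])
  di <- (i - centre[1]) / semi_axes[1]
  dj <- (j - centre[2]) / semi_axes[2]
  dk <- (k - centre[3]) / semi_axes[3]
  outer(outer(di^2, dj^2, `+`), dk^2, `+`) <= 1
}

#' Critical-region mask of a cohort spec
#' @param spec A `lesion_cohort_spec`.
#' @return Logical 3D array marking the planted critical region.
#' @export
critical_region_mask <- function(spec) {
  ctr_vox <- (spec$critical_centre_mm - spec$origin_mm) / spec$voxel_size_mm + 1
  r_vox <- spec$critical_radius_mm / spec$voxel_size_mm
  ellipsoid_mask(spec$grid_shape, ctr_vox, rep(r_vox, 3))
}

#' Generate a synthetic lesion cohort
#'
#' Each patient receives one random ellipsoidal lesion (centre scattered
#' around the critical-region centroid, semi-axes uniform over
#' `lesion_radius_range`). A patient is impaired iff the lesion overlaps the
#' critical region by at least one voxel; the label is then flipped with
#' probability `impairment_noise`. Cohorts in which fewer than 2 patients
#' lesion the critical region, or in which all labels coincide, are
#' resampled.
#'
#' @param spec A `lesion_cohort_spec`.
#' @param seed Integer seed.
#' @param max_resample Resampling cap before erroring.
#' @return An object of class `lesion_cohort`: list with `masks` (list of
#'   uint-like 0/1 3D arrays), `impaired` (logical), `patient_ids`, `spec`,
#'   and `true_overlap` (pre-noise overlap indicator).
#' @export
generate_lesion_cohort <- function(spec, seed = 1L, max_resample = 200) {
  stopifnot(inherits(spec, "lesion_cohort_spec"))
  rng <- new_rng(seed)
  crit <- critical_region_mask(spec)
  ctr_vox <- (spec$critical_centre_mm - spec$origin_mm) / spec$voxel_size_mm + 1
  for (attempt in seq_len(max_resample)) {
    masks <- vector("list", spec$n_patients)
    overlap <- logical(spec$n_patients)
    for (p in seq_len(spec$n_patients)) {
      centre <- pmin(pmax(ctr_vox + rng$rnorm(3, 0, spec$centre_sd), 2),
                     spec$grid_shape - 1)
      semi <- rng$runif(3, spec$lesion_radius_range[1],
                        spec$lesion_radius_range[2])
      m <- ellipsoid_mask(spec$grid_shape, centre, semi)
      masks[[p]] <- array(as.integer(m), dim = spec$grid_shape)
      overlap[p] <- any(m & crit)
    }
    impaired <- overlap
    if (spec$impairment_noise > 0) {
      flip <- rng$runif(spec$n_patients) < spec$impairment_noise
      impaired <- xor(impaired, flip)
    }
    if (sum(overlap) >= 2 && any(impaired) && !all(impaired)) {
      return(structure(list(masks = masks,
                            impaired = impaired,
                            true_overlap = overlap,
                            patient_ids = sprintf("P%02d", seq_len(spec$n_patients)),
                            spec = spec),
                       class = "lesion_cohort"))
    }
  }
  stop("could not generate a cohort meeting the constraints", call. = FALSE)
}

#' Write a lesion cohort to NIfTI files plus a label table
#'
#' One uint8 NIfTI volume per patient (shared MNI-like affine, RAS) and a
#' two-column delimited label file (`patient_id`, `impaired`).
#'
#' @param cohort A `lesion_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_lesion_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  aff[1:3, 4] <- spec$origin_mm
  paths <- character(length(cohort$masks))
  for (p in seq_along(cohort$masks)) {
    img <- RNifti::asNifti(cohort$masks[[p]], datatype = "uint8")
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    paths[p] <- file.path(dir, paste0(cohort$patient_ids[p], ".nii.gz"))
    RNifti::writeNifti(img, paths[p])
  }
  lab <- data.frame(patient_id = cohort$patient_ids,
                    impaired = as.integer(cohort$impaired))
  lab_path <- file.path(dir, "labels.csv")
  utils::write.csv(lab, lab_path, row.names = FALSE)
  invisible(c(paths, lab_path))
}

#' Read a lesion cohort from NIfTI masks and a label table
#'
#' @param mask_paths NIfTI file paths, one binary mask per patient.
#' @param label_path CSV with columns `patient_id`, `impaired` (0/1), in the
#'   same order or matched by file base name.
#' @return A `lesion_cohort` (with `spec = NULL`; the affine is taken from
#'   the first image and stored as `affine`).
#' @export
read_lesion_cohort <- function(mask_paths, label_path) {
  labs <- utils::read.csv(label_path, stringsAsFactors = FALSE)
  imgs <- lapply(mask_paths, RNifti::readNifti)
  shapes <- vapply(imgs, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(shapes)) != 1) {
    stop("lesion masks do not share a common grid", call. = FALSE)
  }
  ids <- sub("\\.nii(\\.gz)?$", "", basename(mask_paths))
  m <- match(ids, labs$patient_id)
  if (anyNA(m)) stop("labels missing for some patients", call. = FALSE)
  structure(list(masks = lapply(imgs, function(x) array(as.integer(x > 0), dim(x))),
                 impaired = as.logical(labs$impaired[m]),
                 patient_ids = ids,
                 affine = RNifti::xform(imgs[[1]]),
                 spec = NULL),
            class = "lesion_cohort")
}
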