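#' Relative BLANK/STEP detection threshold
#'
#' Ratio of the BLANK-condition 75% threshold to the STEP-condition
#' threshold for the same saccade direction. Values below 1 indicate the
#' expected perceptual benefit of target blanking; a ratio near or above 1
#' marks a missing blanking benefit.
#'
#' @param thr_blank,thr_step Thresholds in degrees, both positive.
#' @return The dimensionless ratio BLANK/STEP.
#' @export
relative_threshold <- function(thr_blank, thr_step) {
  if (any(thr_blank <= 0) || any(thr_step <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  thr_blank / thr_step
}

#' Classify a score against control norms
#'
#' A measure is deficient when it falls beyond 1.96 control SDs of the
#' control mean: two-sided (`|value - mean| > 1.96 * sd`) or upper one-sided
#' (`value > mean + 1.96 * sd`). Boundary equality is not impaired.
#'
#' @param value Observed score(s).
#' @param norms List or data frame with `mean` and `sd` of the control
#'   sample (`sd > 0`).
#' @param sided `"two_sided"` or `"upper"`.
#' @param z_crit Criterion multiplier (default 1.96).
#' @return Logical impairment flag(s).
#' @export
classify_deficit <- function(value, norms, sided = c("two_sided", "upper"),
                             z_crit = 1.96) {
  sided <- match.arg(sided)
  stopifnot(norms$sd > 0)
  if (sided == "two_sided") {
    abs(value - norms$mean) > z_crit * norms$sd
  } else {
    value > norms$mean + z_crit * norms$sd
  }
}

#' Correlation between binned targeting error and perceptual report
#'
#' Sorts BLANK-condition trials of one direction by their hypometria error
#' (positive = saccade landed short), splits them into `n_bins` contiguous
#' bins of equal sample size (remainder trials assigned to the lowest-error
#' bins), and correlates the per-bin mean error with the per-bin proportion
#' of forward reports (Pearson, two-sided, `df = n_bins - 2`). An observer
#' who cannot monitor its own motor error misattributes undershoots to
#' forward target jumps, producing a positive correlation; intact monitoring
#' predicts none.
#'
#' @param errors Per-trial hypometria errors, degrees.
#' @param reports Per-trial reports, `"forward"`/`"backward"`.
#' @param n_bins Number of equal-sample bins (default 8).
#' @return A list with `r`, `p`, `n_bins`, the per-bin table, and a
#'   `degenerate` flag (zero variance in either binned variable; then `r` is
#'   NA and `p` is 1).
#' @export
error_bin_correlation <- function(errors, reports, n_bins = 8) {
  keep <- !is.na(errors) & reports %in% c("forward", "backward")
  errors <- errors[keep]
  reports <- reports[keep]
  n <- length(errors)
  if (n < n_bins) stop("fewer trials than bins", call. = FALSE)
  ord <- order(errors)
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1, rem), rep(0, n_bins - rem))
  bin <- rep(seq_len(n_bins), times = sizes)
  idx <- ord
  binned <- data.frame(
    bin = seq_len(n_bins),
    mean_error = tapply(errors[idx], bin, mean),
    prop_forward = tapply(reports[idx] == "forward", bin, mean),
    n = sizes)
  if (stats::sd(binned$mean_error) == 0 || stats::sd(binned$prop_forward) == 0) {
    return(list(r = NA_real_, p = 1, n_bins = n_bins, bins = binned,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(binned$mean_error, binned$prop_forward,
                        method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_bins = n_bins,
       bins = binned, degenerate = FALSE)
}

#' Per-subject deficit scores
#'
#' Derives, from one subject's psychometric fits and trial table, the three
#' individual-level measures: the BLANK/STEP relative threshold per
#' direction, the BLANK threshold asymmetry (rightward minus leftward), and
#' the 8-bin error-attribution correlation per direction (BLANK trials).
#'
#' @param fits Output of `fit_subject()` for this subject.
#' @param trials The subject's trial table (needs `hypometria_error`, e.g.
#'   from `targeting_metrics()`, or `motor_error` as fallback is NOT used —
#'   landings define the error).
#' @param n_bins Bins for the error-attribution analysis.
#' @return A one-row data frame of scores (thresholds per cell, relative
#'   thresholds, asymmetry, correlation r and p per direction).
#' @export
subject_scores <- function(fits, trials, n_bins = 8) {
  thr <- function(cond, dir)
    fits$threshold[fits$condition == cond & fits$direction == dir]
  if (!"hypometria_error" %in% names(trials)) {
    trials <- targeting_metrics(trials)$trials
  }
  cors <- lapply(c("leftward", "rightward"), function(dir) {
    sel <- trials$condition == "BLANK" & trials$direction == dir &
      (if ("included" %in% names(trials)) trials$included else TRUE)
    error_bin_correlation(trials$hypometria_error[sel],
                          trials$report[sel], n_bins = n_bins)
  })
  data.frame(
    thr_step_left = thr("STEP", "leftward"),
    thr_step_right = thr("STEP", "rightward"),
    thr_blank_left = thr("BLANK", "leftward"),
    thr_blank_right = thr("BLANK", "rightward"),
    rel_thr_left = relative_threshold(thr("BLANK", "leftward"),
                                      thr("STEP", "leftward")),
    rel_thr_right = relative_threshold(thr("BLANK", "rightward"),
                                       thr("STEP", "rightward")),
    asymmetry = thr("BLANK", "rightward") - thr("BLANK", "leftward"),
    cor_r_left = cors[[1]]$r, cor_p_left = cors[[1]]$p,
    cor_r_right = cors[[2]]$r, cor_p_right = cors[[2]]$p)
}

#' Cohort deficit profiles and control norms
#'
#' Builds control norms (mean, SD per measure) from the control subjects
#' only, then classifies every subject: relative thresholds upper one-sided
#' (impaired = missing blanking benefit, value above control mean + 1.96 SD),
#' asymmetry two-sided (beyond the +/-1.96 SD interval), and error
#' attribution by the significance of the 8-bin correlation (p < alpha).
#'
#' @param scores Data frame of per-subject scores (rows as from
#'   `subject_scores()`), with a `subject` id column.
#' @param control_ids Subject ids forming the control sample (>= 2).
#' @param alpha Significance level for the attribution correlation.
#' @param z_crit Criterion multiplier for the norm-based measures.
#' @return A list with `profiles` (scores plus impairment flags) and
#'   `norms` (per-measure control mean/SD).
#' @export
cohort_profiles <- function(scores, control_ids, alpha = 0.05,
                            z_crit = 1.96) {
  stopifnot("subject" %in% names(scores))
  ctrl <- scores[scores$subject %in% control_ids, ]
  if (nrow(ctrl) < 2) stop("need at least 2 control subjects", call. = FALSE)
  norm_of <- function(v) list(mean = mean(v), sd = stats::sd(v),
                              n = length(v))
  norms <- list(rel_thr_left = norm_of(ctrl$rel_thr_left),
                rel_thr_right = norm_of(ctrl$rel_thr_right),
                asymmetry = norm_of(ctrl$asymmetry))
  scores$impaired_rel_left <- classify_deficit(scores$rel_thr_left,
                                               norms$rel_thr_left,
                                               "upper", z_crit)
  scores$impaired_rel_right <- classify_deficit(scores$rel_thr_right,
                                                norms$rel_thr_right,
                                                "upper", z_crit)
  scores$impaired_asymmetry <- classify_deficit(scores$asymmetry,
                                                norms$asymmetry,
                                                "two_sided", z_crit)
  scores$impaired_attr_left <- !is.na(scores$cor_p_left) &
    scores$cor_p_left < alpha
  scores$impaired_attr_right <- !is.na(scores$cor_p_right) &
    scores$cor_p_right < alpha
  scores$is_control <- scores$subject %in% control_ids
  list(profiles = scores, norms = norms)
}
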