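test_that("relative thresholds reproduce the reference ratios", {
  # a clear blanking benefit vs an absent one
  expect_equal(relative_threshold(0.84, 1.88), 0.447, tolerance = 1e-3)
  expect_equal(relative_threshold(1.33, 1.34), 0.993, tolerance = 1e-3)
  expect_equal(relative_threshold(1, 1), 1)
  expect_error(relative_threshold(-1, 2), "positive")
})

test_that("classification applies the 1.96 SD rule with strict boundaries", {
  norms <- list(mean = 0.20, sd = 0.35)   # control asymmetry norms
  expect_true(classify_deficit(1.0, norms, "two_sided"))    # cutoff 0.886
  expect_false(classify_deficit(0.20, norms, "two_sided"))
  expect_false(classify_deficit(0.20 + 1.96 * 0.35, norms, "two_sided"))
  expect_false(classify_deficit(0.20 + 1.96 * 0.35, norms, "upper"))
  expect_true(classify_deficit(-0.7, norms, "two_sided"))
  expect_false(classify_deficit(-0.7, norms, "upper"))
  # scale equivariance
  for (c_scale in c(0.1, 3)) {
    expect_equal(
      classify_deficit(1.0 * c_scale,
                       list(mean = 0.2 * c_scale, sd = 0.35 * c_scale),
                       "two_sided"),
      classify_deficit(1.0, norms, "two_sided"))
  }
})

test_that("error-bin correlation is invariant to error offsets and degenerate-safe", {
  set.seed(9)
  errors <- rnorm(203)
  reports <- ifelse(runif(203) < plogis(errors), "forward", "backward")
  e1 <- error_bin_correlation(errors[1:200], reports[1:200])
  e2 <- error_bin_correlation(errors[1:200] + 10, reports[1:200])
  expect_equal(e1$r, e2$r, tolerance = 1e-12)
  expect_equal(e1$p, e2$p, tolerance = 1e-12)
  expect_equal(sum(e1$bins$n), 200)
  expect_equal(length(unique(e1$bins$n)), 1L)   # 200 divides into 8 evenly
  # remainder goes to the lowest-error bins
  e3 <- error_bin_correlation(errors, reports)
  expect_equal(e3$bins$n, c(26, 26, 26, 25, 25, 25, 25, 25))
  # constant reports: zero variance in proportions
  e4 <- error_bin_correlation(errors[1:200], rep("forward", 200))
  expect_true(e4$degenerate)
  expect_equal(e4$p, 1)
  expect_error(error_bin_correlation(errors[1:5], reports[1:5]), "fewer")
})

test_that("an uncoupled observer shows the attribution failure; a coupled one does not", {
  sig_pos <- function(lam, seeds) {
    vapply(seeds, function(s) {
      p <- observer_params(cd_coupling = lam, cd_sd = 0.3)
      tb <- sim_blank_trials(p, seed = s)
      tm <- targeting_metrics(tb)$trials
      ec <- error_bin_correlation(tm$hypometria_error[tm$included],
                                  tm$report[tm$included])
      !is.na(ec$r) && ec$r > 0 && ec$p < 0.05
    }, logical(1))
  }
  expect_gte(sum(sig_pos(0, 1:10)), 9)
  expect_lte(sum(sig_pos(1, 1:10)), 1)
})

test_that("the asymmetry score flips sign when directions are swapped", {
  thr <- data.frame(condition = rep(c("STEP", "BLANK"), each = 2),
                    direction = rep(c("leftward", "rightward"), 2),
                    threshold = c(1.5, 1.4, 0.6, 1.1))
  a_fwd <- thr$threshold[4] - thr$threshold[3]
  expect_equal(a_fwd, 0.5)
  expect_equal(thr$threshold[3] - thr$threshold[4], -a_fwd)
})

test_that("cohort profiling builds norms from controls and flags a planted patient", {
  subj_scores <- function(params, id, seed) {
    tb <- simulate_subject(params, seed = seed)
    tb <- targeting_metrics(tb)$trials
    sc <- subject_scores(fit_subject(tb), tb)
    sc$subject <- id
    sc
  }
  controls <- lapply(1:6, function(i)
    subj_scores(observer_preset("control"), sprintf("C%02d", i), seed = i))
  patient <- subj_scores(
    list(leftward = observer_preset("control"),
         rightward = observer_preset("thalamic")),
    "P01", seed = 77)
  scores <- do.call(rbind, c(controls, list(patient)))
  prof <- cohort_profiles(scores, control_ids = sprintf("C%02d", 1:6))
  pr <- prof$profiles
  # norms computed from controls only
  expect_equal(prof$norms$asymmetry$n, 6L)
  expect_equal(prof$norms$asymmetry$mean,
               mean(pr$asymmetry[pr$is_control]))
  # the planted right-direction deficit is picked up
  p_row <- pr[pr$subject == "P01", ]
  expect_true(p_row$impaired_asymmetry || p_row$impaired_rel_right)
  expect_true(p_row$impaired_attr_right)
  expect_error(cohort_profiles(scores, control_ids = "C01"), "at least 2")
})
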