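test_that("the Liebermeister test matches its exact-enumeration anchors", {
  # perfectly concordant 3+3 table: augmented (4,0,0,4) upper tail = 1/70
  lt <- liebermeister_test(3, 0, 0, 3)
  expect_equal(lt$p, 1 / 70, tolerance = 1e-12)
  # less conservative than Fisher on the raw table (1/20)
  fisher <- fisher.test(matrix(c(3, 0, 0, 3), 2), alternative = "greater")$p.value
  expect_lt(lt$p, fisher)
  # flat table carries no evidence in the impaired direction (exactly 1/2:
  # the augmented (2,1,1,2) upper tail is 10/20)
  expect_equal(liebermeister_test(1, 1, 1, 1)$p, 0.5, tolerance = 1e-12)
  expect_error(liebermeister_test(2, 2, 0, 0), "same label")
  expect_error(liebermeister_test(0, 2, 0, 2), "lesion status")
  # z sign convention: lesion-with-impairment gives positive z
  expect_gt(liebermeister_test(4, 1, 1, 4)$z, 0)
  expect_lt(liebermeister_test(1, 4, 4, 1)$z, 0)
})

test_that("Liebermeister equals the uniform-prior Bayesian oracle and bounds Fisher", {
  # exhaustive over all tables with n <= 8 here (full n <= 12 sweep runs in
  # the acceptance suite)
  for (n in 2:8) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + cc == 0 || b + d == 0 || a + b == 0 || cc + d == 0) next
      p_lieb <- liebermeister_test(a, b, cc, d)$p
      expect_lt(abs(p_lieb - liebermeister_bayes_oracle(a, b, cc, d)), 1e-8)
      p_fisher <- fisher.test(matrix(c(a, cc, b, d), 2),
                              alternative = "greater")$p.value
      expect_lte(p_lieb, p_fisher + 1e-12)
    }
  }
})

test_that("two-sided p doubles the smaller tail and caps at one", {
  one <- liebermeister_test(3, 0, 0, 3)$p
  expect_equal(liebermeister_test(3, 0, 0, 3, sided = "two_sided")$p,
               2 * one)
  expect_lte(liebermeister_test(1, 1, 1, 1, sided = "two_sided")$p, 1)
})

test_that("overlap maps equal the brute-force per-voxel sum", {
  spec <- lesion_cohort_spec()
  co <- generate_lesion_cohort(spec, seed = 12)
  om <- overlap_map(co)
  brute <- array(0L, spec$grid_shape)
  for (m in co$masks) brute <- brute + m
  expect_identical(om, array(as.integer(brute), spec$grid_shape))
  expect_identical(overlap_map(co, 1), co$masks[[1]])
  # two disjoint masks never exceed count 1
  co2 <- co; co2$masks <- list(co$masks[[1]], 1L - co$masks[[1]])
  co2$impaired <- c(TRUE, FALSE); co2$patient_ids <- c("A", "B")
  expect_lte(max(overlap_map(co2)), 1L)
})

test_that("subtraction maps are thresholded and antisymmetric", {
  spec <- lesion_cohort_spec(n_patients = 4)
  co <- generate_lesion_cohort(spec, seed = 3)
  co$impaired <- c(TRUE, TRUE, FALSE, FALSE)
  sm <- subtraction_map(co, threshold_pct = 15)
  expect_true(all(sm[sm != 0] >= 15 | sm[sm != 0] <= -15))
  # a voxel lesioned in 2/2 impaired and 0/2 unimpaired reads +100
  both_imp <- co$masks[[1]] & co$masks[[2]] & !co$masks[[3]] & !co$masks[[4]]
  if (any(both_imp)) expect_true(all(sm[both_imp] == 100))
  co_swap <- co; co_swap$impaired <- !co$impaired
  expect_equal(subtraction_map(co_swap, 15), -sm)
  co_bad <- co; co_bad$impaired <- rep(TRUE, 4)
  expect_error(subtraction_map(co_bad), "non-empty")
})

test_that("the lesion-symptom map respects the minimum-lesion rule and group labels", {
  spec <- lesion_cohort_spec()
  co <- generate_lesion_cohort(spec, seed = 7)
  vl <- vlsm_map(co, min_lesioned = 2)
  counts <- overlap_map(co)
  expect_false(any(vl$included_mask & counts < 2))
  expect_true(all(is.na(vl$p_map[!vl$included_mask])))
  expect_true(all(vl$p_map[vl$included_mask] > 0 &
                  vl$p_map[vl$included_mask] <= 1))
  # permutation equivariance over patients
  perm <- c(5, 3, 1, 2, 4, 14, 7, 6, 13, 9, 8, 12, 11, 10)
  co_p <- co
  co_p$masks <- co$masks[perm]
  co_p$impaired <- co$impaired[perm]
  co_p$patient_ids <- co$patient_ids[perm]
  vl_p <- vlsm_map(co_p, min_lesioned = 2)
  expect_equal(vl_p$z_map, vl$z_map)
  expect_equal(vl_p$peak$index, vl$peak$index)
})

test_that("the peak voxel recovers the planted critical region", {
  spec <- lesion_cohort_spec()
  crit <- which(critical_region_mask(spec), arr.ind = TRUE)
  hits <- vapply(1:10, function(s) {
    vl <- vlsm_map(generate_lesion_cohort(spec, seed = s))
    min(apply(abs(sweep(crit, 2, vl$peak$index)), 1, max)) <= 1
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("recovery degrades monotonically with label noise", {
  rate_at <- function(noise) {
    spec <- lesion_cohort_spec(impairment_noise = noise)
    crit <- which(critical_region_mask(spec), arr.ind = TRUE)
    mean(vapply(1:8, function(s) {
      co <- generate_lesion_cohort(spec, seed = 100 + s)
      vl <- vlsm_map(co)
      !is.null(vl$peak) &&
        min(apply(abs(sweep(crit, 2, vl$peak$index)), 1, max)) <= 1
    }, logical(1)))
  }
  rates <- c(rate_at(0), rate_at(0.1), rate_at(0.3))
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("the power map contains every significant voxel and handles no-contrast voxels", {
  for (s in 1:5) {
    co <- generate_lesion_cohort(lesion_cohort_spec(), seed = 40 + s)
    vl <- vlsm_map(co)
    pw <- power_map(co)
    expect_false(any(vl$significant_mask & !pw$powered_mask))
  }
  # a voxel lesioned in everyone has no contrast: unpowered
  co <- generate_lesion_cohort(lesion_cohort_spec(n_patients = 4), seed = 2)
  all_vox <- array(1L, dim(co$masks[[1]]))
  co$masks <- lapply(co$masks, function(m) all_vox)
  pw <- power_map(co)
  expect_false(any(pw$powered_mask))
  expect_true(all(is.na(pw$min_p_map)))
})

test_that("atlas-label association matches the closed-form 2x2 chi-square", {
  spec <- lesion_cohort_spec()
  co <- generate_lesion_cohort(spec, seed = 9)
  # perfectly confounded label: lesion presence in label = impairment,
  # with a 7/7 split the statistic is exactly n = 14
  at <- synthetic_atlas(spec)
  co$impaired <- c(rep(TRUE, 7), rep(FALSE, 7))
  lab <- array(0L, spec$grid_shape); lab[1, 1, 1] <- 1L
  co$masks <- lapply(seq_len(14), function(p) {
    m <- array(0L, spec$grid_shape)
    if (p <= 7) m[1, 1, 1] <- 1L else m[2, 2, 2] <- 1L
    m
  })
  res <- label_association(co, lab)
  expect_equal(res$chisq[res$label == 1], 14, tolerance = 1e-9)
  # untested labels are skipped with a note
  lab2 <- lab; lab2[5, 5, 5] <- 2L
  res2 <- label_association(co, lab2)
  expect_false(res2$tested[res2$label == 2])
  # random tables against the closed form n(ad-bc)^2 / product of margins
  set.seed(77)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))$statistic
    a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * (a + cc) * (b + d))
    expect_equal(unname(chi), closed, tolerance = 1e-9)
  }
})
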