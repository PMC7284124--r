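test_that("cohort generation is deterministic and honours the design", {
  sp <- cohort_spec(n_control = 30, n_clinical = 40, n_rois = 25, seed = 7)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1, c2)

  expect_equal(nrow(c1$features), 70)
  expect_equal(ncol(c1$features), 25)
  expect_equal(sum(c1$records$group == "control"), 30)
  expect_setequal(unique(c1$records$primary_diagnosis[c1$records$group == "clinical"]),
                  c("ASD", "ADHD"))
  expect_true(all(c1$records$primary_diagnosis[c1$records$group == "control"] == "none"))
  expect_true(all(!c1$records$dual_diagnosis[c1$records$group == "control"]))
  # every clinical subject carries exactly one subtype label
  expect_setequal(names(c1$truth$subtype),
                  c1$records$subject_id[c1$records$group == "clinical"])
  expect_true(all(c1$truth$subtype %in% 1:2))
  # affected sets are subsets of the ROI universe
  for (s in c1$truth$affected_rois)
    expect_true(all(s %in% colnames(c1$features)))
})

test_that("null cohorts show no group separation beyond sampling noise", {
  ch <- small_cohort(seed = 3, effect_size = 0, n_control = 60, n_clinical = 60,
                     n_rois = 50)
  adj <- adjust_covariates(ch$features, ch$records)
  is_clin <- ch$records$group == "clinical"
  x <- unclass(adj)
  se <- sqrt(apply(x[is_clin, ], 2, var) / sum(is_clin) +
             apply(x[!is_clin, ], 2, var) / sum(!is_clin))
  z <- abs(colMeans(x[is_clin, ]) - colMeans(x[!is_clin, ])) / se
  expect_true(all(z < 4))
  # t-tests reject at roughly the nominal 5% rate across ROIs
  res <- two_sample_tests(x, rownames(x)[is_clin], rownames(x)[!is_clin])
  expect_lt(mean(res$p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(res)))
})

test_that("planted effects are recoverable at the designed magnitude", {
  sp <- cohort_spec(n_control = 200, n_clinical = 200, n_rois = 60,
                    n_subtypes = 1, affected_fraction = 0.3,
                    effect_size = 1.0, noise_sd = 1, age_slope = 0,
                    handedness_slope = 0, seed = 11)
  ch <- generate_cohort(sp)
  x <- unclass(ch$features)
  is_clin <- ch$records$group == "clinical"
  aff <- ch$truth$affected_rois[[1]]
  d <- vapply(aff, function(r) {
    (mean(x[is_clin, r]) - mean(x[!is_clin, r])) /
      sqrt((var(x[is_clin, r]) + var(x[!is_clin, r])) / 2)
  }, numeric(1))
  expect_true(all(abs(d - 1.0) < 0.5))  # per-ROI sampling noise
  expect_lt(abs(mean(d) - 1.0), 0.2)    # cohort-level effect calibration
})

test_that("spec validation rejects impossible designs", {
  expect_error(cohort_spec(n_subtypes = 0), "n_subtypes")
  expect_error(cohort_spec(n_clinical = 3, n_subtypes = 5), "exceeds")
  expect_error(cohort_spec(n_rois = 10, affected_fraction = 0.01,
                           effect_size = 1), "affected_fraction")
  expect_error(cohort_spec(noise_sd = 0), "noise_sd")
  expect_error(cohort_spec(diagnosis_mix = c(0.5, 0.6, 0.7)), "diagnosis_mix")
  # zero effect with zero affected ROIs is legal (pure null design)
  expect_s3_class(cohort_spec(n_rois = 10, affected_fraction = 0,
                              effect_size = 0), "cohort_spec")
})

test_that("atlas mappings partition ROIs into non-empty networks", {
  m <- generate_atlas_mapping(7, 7, seed = 1)
  expect_equal(unname(table(m$network)), rep(1L, 7), ignore_attr = TRUE)

  m2 <- generate_atlas_mapping(400, 7, seed = 2)
  expect_equal(nrow(m2), 400)
  expect_equal(length(unique(m2$network)), 7)
  expect_equal(sum(table(m2$network)), 400)

  expect_identical(generate_atlas_mapping(50, 7, seed = 5),
                   generate_atlas_mapping(50, 7, seed = 5))
  expect_error(generate_atlas_mapping(5, 7), "exceeds")
})

test_that("crosswalks are row-stochastic and respect nesting", {
  ma <- generate_atlas_mapping(12, 3, seed = 1, atlas_id = "A")
  mb <- generate_atlas_mapping(12, 3, seed = 2, atlas_id = "B")
  cw <- generate_crosswalk(ma, mb)
  expect_equal(unname(rowSums(cw)), rep(1, 12))
  # same-size equal-width partitions coincide: identity
  expect_equal(unname(cw), diag(12), ignore_attr = TRUE)

  m4 <- generate_atlas_mapping(4, 2, seed = 1)
  m2 <- generate_atlas_mapping(2, 2, seed = 1)
  nested <- generate_crosswalk(m4, m2)
  expect_equal(unname(nested),
               matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2), ignore_attr = TRUE)
  expect_true(all(nested %in% c(0, 1)))
})

test_that("feature projection averages within target regions", {
  ma <- generate_atlas_mapping(4, 2, seed = 1)
  mb <- generate_atlas_mapping(2, 2, seed = 1)
  cw <- generate_crosswalk(ma, mb)
  vals <- matrix(c(1, 3, 5, 7), 1, 4,
                 dimnames = list("s1", ma$roi_id))
  ft <- feature_table(vals, "CT", "A")
  proj <- project_features(ft, cw)
  expect_equal(unname(unclass(proj)), matrix(c(2, 6), 1, 2),
               ignore_attr = TRUE)
})
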