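test_that("phantom generation is deterministic and geometrically nested", {
  spec <- small_spec(seed = 7)
  b1 <- generate_phantom(spec)
  b2 <- generate_phantom(spec)
  for (m in names(b1$modalities))
    expect_identical(b1$modalities[[m]]$data, b2$modalities[[m]]$data)
  expect_identical(b1$followup_enhancing_mask$data, b2$followup_enhancing_mask$data)

  # recurrence subset of peritumor subset of brain; cavity and peritumor disjoint
  rec <- b1$peritumor_mask$data & b1$followup_enhancing_mask$data
  expect_true(all(b1$peritumor_mask$data[rec == 1] == 1))
  expect_true(all(b1$brain_mask$data[b1$peritumor_mask$data == 1] == 1))
  expect_equal(sum(b1$cavity_mask$data & b1$peritumor_mask$data), 0)
  # the bulge makes the follow-up mask extend beyond the peritumor
  expect_gt(sum(b1$followup_enhancing_mask$data), sum(rec))
})

test_that("full-angle, full-depth recurrence covers the whole shell", {
  spec <- small_spec()
  spec$recurrence_solid_angle_deg <- 360
  spec$recurrence_depth_mm <- spec$shell_thickness_mm
  b <- generate_phantom(spec)
  lab <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
  expect_equal(lab$counts[["nonrecurrence"]], 0L)
  expect_equal(lab$counts[["recurrence"]], recurmap:::mask_count(b$peritumor_mask))
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 16), cavity_radius_mm = 20),
               "degenerate|larger than grid")
  expect_error(phantom_spec(recurrence_depth_mm = 50, shell_thickness_mm = 10),
               "recurrence_depth")
  expect_error(phantom_spec(cavity_radius_mm = -1), "positive")
})

test_that("zero effect size yields statistically indistinguishable classes", {
  # Monte-Carlo over seeds: per-seed standardized class difference of the
  # T1ce mean intensity, tested against zero across seeds (spatially
  # correlated fields make a naive within-case test invalid)
  d <- sapply(1:20, function(s) {
    b <- generate_phantom(small_spec(effect_size = 0, seed = 1000 + s))
    lab <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
    v <- b$modalities$T1ce$data[b$peritumor_mask$data == 1]
    y <- lab$data[lab$data != 255L]
    (mean(v[y == 1]) - mean(v[y == 0])) /
      sqrt((var(v[y == 1]) + var(v[y == 0])) / 2)
  })
  expect_gt(t.test(d)$p.value, 0.01)
})

test_that("the configured effect size is recovered from the voxels", {
  # standardize by the nonrecurrence-class SD: the recurrence region is
  # small relative to the field correlation length, so its within-region
  # SD underestimates the marginal scale
  d <- sapply(1:10, function(s) {
    b <- generate_phantom(small_spec(effect_size = 1.5, seed = 2000 + s))
    lab <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
    v <- b$modalities$T1ce$data[b$peritumor_mask$data == 1]   # multiplier 1
    y <- lab$data[lab$data != 255L]
    (mean(v[y == 1]) - mean(v[y == 0])) / sd(v[y == 0])
  })
  expect_lt(abs(mean(d) - 1.5) / 1.5, 0.2)
})

test_that("cohorts are reproducible with distinct per-case geometry", {
  spec <- small_spec()
  co1 <- generate_cohort(4, 2, spec, seed = 5)
  co2 <- generate_cohort(4, 2, spec, seed = 5)
  ids <- sapply(c(co1$train, co1$test), function(b) b$case_id)
  expect_equal(length(unique(ids)), 6)
  dirs <- t(sapply(c(co1$train, co1$test), function(b) b$meta$direction))
  expect_equal(nrow(unique(round(dirs, 6))), 6)
  expect_identical(co1$train[[2]]$modalities$FLAIR$data,
                   co2$train[[2]]$modalities$FLAIR$data)
  co3 <- generate_cohort(2, 1, spec, seed = 6)
  expect_false(identical(co1$train[[1]]$modalities$T1w$data,
                         co3$train[[1]]$modalities$T1w$data))
})

test_that("case bundles round-trip through the NIfTI directory layout", {
  b <- generate_phantom(small_spec(seed = 31), case_id = "rt_case")
  dir <- tempfile()
  write_case_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "rt_case", "T1ce.nii.gz")))
  expect_true(file.exists(file.path(dir, "rt_case", "phantom.json")))
  b2 <- read_case_bundle(file.path(dir, "rt_case"))
  expect_equal(b2$modalities$ADC$data, b$modalities$ADC$data, tolerance = 1e-12)
  expect_identical(b2$peritumor_mask$data, b$peritumor_mask$data)
  expect_equal(b2$meta$spec$effect_size, 2)
})

test_that("downstream voxel AUC increases monotonically with effect size", {
  auc_at <- function(es, seed) {
    cfg <- run_config(phantom = small_spec(effect_size = es, seed = NULL),
                      n_train = 2, n_test = 1, algorithms = "catboost",
                      seed = seed)
    suppressMessages(cohort <- run_simulate(cfg))
    suppressMessages(tr <- run_train(cfg, cohort))
    b <- cohort$test[[1]]
    suppressMessages(pr <- run_predict(cfg, tr$models[[1]], b))
    truth <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
    voxel_metrics(pr$corrected, pr$predicted_mask, truth)$auc
  }
  means <- sapply(c(0, 1, 2), function(es)
    mean(sapply(1:5, function(s) auc_at(es, seed = 300 + s))))
  expect_lt(means[1], means[2])
  expect_lt(means[2], means[3])
})
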