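test_that("discretization follows equal-width binning", {
  expect_equal(discretize(c(0, 1, 2, 3), 2), c(1L, 1L, 2L, 2L))
  expect_equal(discretize(rep(4.2, 10), 8), rep(1L, 10))
  set.seed(2)
  v <- rnorm(500)
  for (nb in c(2, 16, 64))
    expect_true(all(discretize(v, nb) %in% seq_len(nb)))
})

test_that("first-order features match hand arithmetic and the base-R oracle", {
  f <- first_order_features(c(1, 2, 3, 4))
  expect_equal(f[["mean"]], 2.5)
  expect_equal(f[["variance"]], 1.25)      # population convention
  expect_equal(f[["range"]], 3)

  fc <- first_order_features(rep(2, 9))
  expect_equal(fc[["variance"]], 0)
  expect_equal(fc[["entropy"]], 0)
  expect_equal(fc[["uniformity"]], 1)
  expect_equal(fc[["skewness"]], 0)

  expect_equal(first_order_features(c(-3, 0, 3))[["skewness"]], 0)

  set.seed(14)
  for (i in 1:5) {
    v <- rnorm(50 + i * 13)
    expect_equal(unname(first_order_features(v, 16, voxel_volume_mm3 = 2)),
                 unname(oracle_first_order(v, 16, 2)), tolerance = 1e-12)
  }
})

test_that("texture matrices reproduce known tiny configurations", {
  # constant 3^3 patch: GLCM mass on one diagonal entry, zero contrast
  lev <- array(1L, c(3, 3, 3))
  g <- texture_matrix(lev, "glcm", n_bins = 4)
  for (d in 1:13) {
    s <- g[, , d]
    expect_equal(sum(s[-1, ]) + sum(s[1, -1]), 0)
    expect_gt(s[1, 1], 0)
  }
  expect_equal(texture_features(g)[["contrast"]], 0)
  expect_equal(texture_features(g)[["joint_energy"]], 1)
  expect_equal(texture_features(g)[["joint_entropy"]], 0)
  expect_equal(texture_features(g)[["correlation"]], 1)

  # 1D pattern 1,1,2,2 along x: two runs of length 2 in the x direction
  lev2 <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  r <- texture_matrix(lev2, "glrlm", n_bins = 2)
  expect_equal(r[1, 2, 1], 1)
  expect_equal(r[2, 2, 1], 1)
  expect_equal(sum(r[, , 1]), 2)

  # axial checkerboard: GLCM mass off-diagonal, correlation <= 0
  dm <- c(4, 4, 4)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  lev3 <- array(1L + (rowSums(idx) %% 2L), dm)
  gc <- texture_matrix(lev3, "glcm", n_bins = 2)
  expect_equal(sum(diag(gc[, , 1])), 0)   # axial direction: all mass off-diagonal
  ax <- gc[, , 1, drop = FALSE]           # single axial direction
  attributes(ax)[c("family", "n_bins", "n_valid")] <-
    attributes(gc)[c("family", "n_bins", "n_valid")]
  expect_lte(texture_features(ax, "glcm")[["correlation"]], 0)
})

test_that("every texture feature matches naive brute-force enumeration", {
  set.seed(99)
  dirs <- oracle_dirs()
  n_bins <- 6L
  for (rep in 1:10) {
    patch <- array(rnorm(125), c(5, 5, 5))
    valid <- array(1L, c(5, 5, 5))
    if (rep > 5) valid[sample(125, 30)] <- 0L   # ragged support half the time
    lev <- array(1L, c(5, 5, 5))
    lev[valid == 1L] <- discretize(patch[valid == 1L], n_bins)

    # GLCM, averaged over directions
    go <- sapply(dirs, function(d) {
      cnt <- oracle_glcm_counts(lev, valid, n_bins, d)
      if (sum(cnt) == 0) return(rep(NA_real_, 24))
      oracle_glcm_features(cnt)
    })
    go <- rowMeans(go, na.rm = TRUE)
    gi <- texture_features(texture_matrix(lev, "glcm", n_bins, valid))
    expect_equal(unname(gi), unname(go), tolerance = 1e-8)

    # GLRLM
    Nv <- sum(valid)
    ro <- sapply(dirs, function(d)
      oracle_rl_features(oracle_glrlm_counts(lev, valid, n_bins, d, 5), Nv))
    ri <- texture_features(texture_matrix(lev, "glrlm", n_bins, valid))
    expect_equal(unname(ri), unname(rowMeans(ro)), tolerance = 1e-8)

    # GLSZM
    so <- oracle_rl_features(oracle_glszm_counts(lev, valid, n_bins), Nv)
    si <- texture_features(texture_matrix(lev, "glszm", n_bins, valid))
    expect_equal(unname(si), unname(so), tolerance = 1e-8)

    # NGTDM
    no <- oracle_ngtdm_features(oracle_ngtdm(lev, valid, n_bins))
    ni <- texture_features(texture_matrix(lev, "ngtdm", n_bins, valid))
    expect_equal(unname(ni), unname(no), tolerance = 1e-8)

    # GLDM
    do_ <- oracle_gldm_features(oracle_gldm(lev, valid, n_bins), Nv)
    di <- texture_features(texture_matrix(lev, "gldm", n_bins, valid))
    expect_equal(unname(di), unname(do_), tolerance = 1e-8)
  }
})

test_that("degenerate matrices take analytic limits, not NaN", {
  lev <- array(1L, c(2, 2, 2))
  for (fam in c("glcm", "glrlm", "glszm", "ngtdm", "gldm")) {
    v <- texture_features(texture_matrix(lev, fam, n_bins = 3))
    expect_true(all(is.finite(v)), info = fam)
  }
  # uniform GLCM over L levels: joint entropy 2*log2(L) for the pair distribution
  L <- 4L
  u <- array(0, c(L, L, 13))
  u[, , 1] <- 1
  attr(u, "family") <- "glcm"
  attr(u, "n_bins") <- L
  attr(u, "n_valid") <- 64L
  expect_equal(texture_features(u, "glcm")[["joint_entropy"]], 2 * log2(L))
})

test_that("voxelwise first-order mean map equals a box-filter oracle", {
  g <- rand_grid(c(9, 9, 9), seed = 21)
  mask <- mask_volume(array(1L, c(9, 9, 9)))
  maps <- voxelwise_feature_maps(g, mask, kernel_radius_vox = 1L)
  mean_map <- array(maps$features[, "firstorder_mean"], c(9, 9, 9))
  # normalized box filter with edge clipping, by direct enumeration
  oracle <- array(NA_real_, c(9, 9, 9))
  for (x in 1:9) for (y in 1:9) for (z in 1:9)
    oracle[x, y, z] <- mean(g$data[max(1, x - 1):min(9, x + 1),
                                   max(1, y - 1):min(9, y + 1),
                                   max(1, z - 1):min(9, z + 1)])
  expect_equal(mean_map, oracle, tolerance = 1e-6)
})

test_that("voxelwise maps are translation-equivariant and radius-0 is identity", {
  dm <- c(8, 8, 8)
  set.seed(4)
  a <- array(rnorm(prod(dm)), dm)
  g1 <- voxel_grid(a)
  g2 <- voxel_grid(a[c(2:8, 1), , ])            # shift by one voxel along x
  inner <- array(0L, dm)
  inner[3:6, 3:6, 3:6] <- 1L
  m1 <- voxelwise_feature_maps(g1, mask_volume(inner), kernel_radius_vox = 1L)
  inner2 <- array(0L, dm)
  inner2[2:5, 3:6, 3:6] <- 1L
  m2 <- voxelwise_feature_maps(g2, mask_volume(inner2), kernel_radius_vox = 1L)
  expect_equal(m1$features, m2$features, tolerance = 1e-12)

  m0 <- voxelwise_feature_maps(g1, mask_volume(inner), kernel_radius_vox = 0L)
  expect_equal(as.numeric(m0$features[, "firstorder_mean"]),
               a[inner == 1L], tolerance = 1e-12)
})

test_that("kernels clipped by the support are flagged in QC", {
  dm <- c(8, 8, 8)
  g <- rand_grid(dm)
  target <- array(0L, dm)
  target[1, 1, 1] <- 1L                       # corner voxel
  supp <- array(0L, dm)
  supp[1:2, 1, 1] <- 1L                       # only 2 support voxels
  maps <- voxelwise_feature_maps(g, mask_volume(target),
                                 support = mask_volume(supp),
                                 kernel_radius_vox = 2L)
  expect_true(maps$qc[1])
})

test_that("the manifest counts features as configured", {
  cfg <- feature_config(filters = "original", families = "firstorder")
  expect_equal(nrow(feature_manifest(cfg)), 5 * 19)
  cfg_all <- feature_config(filters = "original", families = "all")
  mf <- feature_manifest(cfg_all)
  expect_equal(nrow(mf), 5 * 94)
  expect_equal(sum(mf$modality == "T1ce"), 94)
  expect_false(anyDuplicated(mf$name) > 0)
  cfg_fb <- feature_config(filters = c("original", "log", "wavelet", "lbp"),
                           families = "all", log_sigma_mm = c(1, 2, 3))
  expect_equal(nrow(feature_manifest(cfg_fb)), 5 * (1 + 3 + 8 + 1) * 94)
})

test_that("feature tables conserve rows, finiteness and labels", {
  b <- generate_phantom(small_spec(seed = 8))
  ft <- build_feature_table(b, feature_config())
  expect_equal(nrow(ft$features), recurmap:::mask_count(b$peritumor_mask))
  expect_true(all(is.finite(ft$features)))
  expect_equal(colnames(ft$features), ft$manifest$name)
  expect_equal(length(ft$labels), nrow(ft$features))

  b$modalities$ADC <- NULL
  expect_error(build_feature_table(b, feature_config()), "ADC")
})
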