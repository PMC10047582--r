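shell_case <- function(seed = 1) {
  b <- generate_phantom(small_spec(seed = seed))
  truth <- derive_labels(b$peritumor_mask, b$followup_enhancing_mask)
  list(b = b, truth = truth)
}

test_that("voxel metrics are exact on perfect and hand-computed predictions", {
  sc <- shell_case()
  y <- recurmap:::label_vector(sc$truth)
  perfect <- probability_map(as.numeric(y), sc$b$peritumor_mask,
                             stage = "corrected")
  pm <- sc$b$peritumor_mask
  pred <- array(0L, dim(pm$data))
  pred[pm$data == 1L][y == 1L] <- 1L
  pred_mask <- mask_volume(pred)
  vm <- voxel_metrics(perfect, pred_mask, sc$truth)
  expect_equal(vm$auc, 1)
  expect_equal(vm$accuracy, 1)
  expect_equal(vm$kappa, 1)

  # confusion counts TP=40 FN=10 FP=20 TN=30 -> accuracy 0.7, kappa 0.4
  bm <- recurmap:::binary_metrics(rep(c(1, 1, 0, 0), c(40, 10, 20, 30)),
                                  rep(c(1, 0, 1, 0), c(40, 10, 20, 30)))
  expect_equal(bm$accuracy, 0.7)
  expect_equal(bm$kappa, 0.4)
  expect_equal(bm$precision, 40 / 60)
  expect_equal(bm$recall, 0.8)
})

test_that("scores independent of truth give chance AUC; pROC agrees", {
  set.seed(55)
  aucs <- sapply(1:10, function(s) {
    y <- rbinom(10000, 1, 0.2)
    auc_score(runif(10000), y)
  })
  expect_true(all(aucs > 0.45 & aucs < 0.55))

  # cross-check the rank formula against an independent implementation
  skip_if_not_installed("pROC")
  for (s in 1:3) {
    set.seed(s)
    y <- rbinom(300, 1, 0.4)
    x <- rnorm(300) + y
    expect_equal(auc_score(x, y),
                 as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("single-class truth yields a reasoned missing AUC", {
  a <- auc_score(runif(10), rep(1, 10))
  expect_true(is.na(a))
  expect_match(attr(a, "reason"), "single-class")
})

test_that("sector partition covers the peritumor disjointly on random geometries", {
  for (s in 1:20) {
    set.seed(s)
    dm <- c(24, 24, 24)
    ctr <- c(12, 12, 12) + round(runif(3, -2, 2))
    rc <- runif(1, 2, 4)
    idx <- arrayInd(seq_len(prod(dm)), dm)
    r <- sqrt(rowSums(sweep(idx, 2, ctr)^2))
    cav <- mask_volume(array(as.integer(r <= rc), dm))
    peri <- mask_volume(array(as.integer(r > rc & r <= rc + runif(1, 3, 6)), dm))
    part <- sector_partition(peri, cav)
    # every peritumoral voxel in exactly one sector
    expect_equal(length(part$ids), recurmap:::mask_count(peri))
    expect_true(all(part$sector[peri$data == 1L] > 0))
    expect_true(all(part$sector[peri$data == 0L] == 0))
    expect_equal(sum(part$catalog$size), recurmap:::mask_count(peri))
  }
})

test_that("a full spherical shell populates all 26 sectors", {
  dm <- c(40, 40, 40)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  r <- sqrt(rowSums(sweep(idx, 2, c(20, 20, 20))^2))
  cav <- mask_volume(array(as.integer(r <= 5), dm))
  peri <- mask_volume(array(as.integer(r > 5 & r <= 14), dm))
  part <- sector_partition(peri, cav)
  expect_equal(sum(part$catalog$size > 0), 26)
})

test_that("axis-aligned and diagonal displacements land in the named sectors", {
  dm <- c(31, 31, 31)
  ctr <- c(16, 16, 16)
  cav <- mask_volume(array(0L, dm))
  cav$data[16, 16, 16] <- 1L
  peri <- mask_volume(array(0L, dm))
  peri$data[16, 26, 16] <- 1L      # +y = anterior under RAS
  peri$data[26, 26, 26] <- 1L      # +x+y+z corner
  part <- sector_partition(peri, cav)
  names <- part$catalog$name[match(part$ids, part$catalog$id)]
  expect_true("anterior" %in% names)
  expect_true("anterior-superior-right" %in% names)
})

test_that("sector activation follows the fractional threshold rule", {
  # one sector of exactly 1000 voxels via a synthetic partition
  dm <- c(20, 20, 20)
  cav <- mask_volume(array(0L, dm)); cav$data[2, 10, 10] <- 1L
  peri <- mask_volume(array(0L, dm))
  peri$data[3:12, 1:10, 1:10] <- 1L   # 1000 voxels, all +x of the centroid-ish
  part <- sector_partition(peri, cav)
  big <- part$catalog$id[which.max(part$catalog$size)]
  sz <- max(part$catalog$size)
  need <- ceiling(0.01 * sz)
  v <- integer(length(part$ids))
  v[which(part$ids == big)[seq_len(need - 1)]] <- 1L
  lab <- sector_labels(part, v, activation_fraction = 0.01)
  nm <- part$catalog$name[part$catalog$id == big]
  expect_false(lab[[nm]])
  v[which(part$ids == big)[seq_len(need)]] <- 1L
  expect_true(sector_labels(part, v, 0.01)[[nm]])
  # empty mask: no sector is positive
  expect_true(all(!sector_labels(part, integer(length(part$ids)), 0.01)))
})

test_that("sector metrics are exact for perfect and complementary predictions", {
  sc <- shell_case(seed = 4)
  part <- sector_partition(sc$b$peritumor_mask, sc$b$cavity_mask)
  y <- recurmap:::label_vector(sc$truth)
  pm <- sc$b$peritumor_mask
  pred <- array(0L, dim(pm$data))
  pred[pm$data == 1L][y == 1L] <- 1L
  scores <- probability_map(as.numeric(y), pm, stage = "corrected")
  sm <- sector_metrics(part, sc$truth, mask_volume(pred), scores)
  expect_equal(sm$accuracy, 1)
  expect_equal(sm$kappa, 1)
  expect_equal(sm$recall, 1)

  # predictions covering exactly the sectors that are NOT truth-positive
  t_sec <- sector_labels(part, as.integer(y == 1L))
  neg_ids <- part$catalog$id[part$catalog$size > 0][!t_sec]
  comp <- array(0L, dim(pm$data))
  comp[part$voxel_index[part$ids %in% neg_ids]] <- 1L
  smc <- sector_metrics(part, sc$truth, mask_volume(comp), scores)
  expect_equal(smc$recall, 0)
  expect_equal(smc$precision, 0)
  expect_true(smc$kappa < 0)
})

test_that("cohort aggregation uses the population SD and tracks missing values", {
  pc <- data.frame(case_id = c("a", "b"), mode = "voxel",
                   auc = c(0.7, 0.9), accuracy = c(0.8, 0.8),
                   precision = c(0.5, 0.7), recall = c(1, 1),
                   f1 = c(0.6, 0.7), kappa = c(0.2, 0.4))
  agg <- aggregate_cohort(pc)
  a <- agg[agg$metric == "auc", ]
  expect_equal(a$mean, 0.8)
  expect_equal(a$sd, 0.1)
  expect_equal(a$formatted, "0.80 ± 0.10")
  expect_equal(agg[agg$metric == "accuracy", ]$sd, 0)

  pc$auc[2] <- NA
  agg2 <- aggregate_cohort(pc)
  a2 <- agg2[agg2$metric == "auc", ]
  expect_equal(a2$n, 1)
  expect_equal(a2$n_missing, 1)
  expect_equal(a2$mean, 0.7)
})
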