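sphere_mask <- function(dm, center, radius, spacing = c(1, 1, 1)) {
  idx <- arrayInd(seq_len(prod(dm)), dm)
  r <- sqrt(rowSums((sweep(idx, 2, center) %*% diag(spacing))^2))
  mask_volume(array(as.integer(r <= radius), dm), spacing)
}

test_that("cavity distances follow unit geometry", {
  dm <- c(9, 9, 9)
  cav <- mask_volume(array(0L, dm))
  cav$data[5, 5, 5] <- 1L
  d <- distance_from_cavity(cav)
  expect_equal(d$data[5, 5, 5], 0)
  expect_equal(d$data[6, 5, 5], 1)          # face neighbour at 1 mm
  expect_equal(d$data[6, 6, 5], sqrt(2))
  expect_equal(d$data[9, 5, 5], 4)

  # anisotropic spacing is honored in world mm
  cav2 <- mask_volume(array(0L, dm), spacing = c(1, 1, 2))
  cav2$data[5, 5, 5] <- 1L
  expect_equal(distance_from_cavity(cav2)$data[5, 5, 6], 2)

  expect_error(distance_from_cavity(mask_volume(array(0L, dm))), "empty")
})

test_that("sphere-cavity distances match analytic geometry", {
  dm <- c(41, 41, 41)
  cav <- sphere_mask(dm, c(21, 21, 21), 10)
  d <- distance_from_cavity(cav)
  idx <- arrayInd(seq_len(prod(dm)), dm)
  r <- sqrt(rowSums(sweep(idx, 2, c(21, 21, 21))^2))
  at18 <- abs(r - 18) < 0.25
  expect_true(all(abs(d$data[at18] - 8) < 0.6))
  # zero on the cavity itself
  expect_true(all(d$data[cav$data == 1L] == 0))
})

test_that("the correction factor is 1 inside the cutoff and decays beyond", {
  cfg <- correction_config(cutoff_mm = 15, decay_rate_per_mm = 0.5)
  mult <- recurmap:::correction_multiplier
  expect_equal(mult(10, cfg), 1)
  expect_equal(mult(15, cfg), 1)             # continuity at the boundary
  expect_equal(mult(20, cfg), exp(-2.5))
  # continuous and nonincreasing in distance
  d <- seq(0, 40, by = 0.01)
  m <- mult(d, cfg)
  expect_true(all(diff(m) <= 1e-12))
  expect_lt(max(abs(diff(m))), 0.01)
})

test_that("correction never increases probabilities and guards its stage", {
  dm <- c(7, 7, 7)
  peri <- sphere_mask(dm, c(4, 4, 4), 3)
  set.seed(5)
  raw <- probability_map(runif(sum(peri$data)), peri)
  d <- seq(0, 30, length.out = sum(peri$data))
  cor <- distance_correction(raw, d)
  expect_true(all(recurmap:::map_values(cor) <=
                    recurmap:::map_values(raw) + 1e-15))
  expect_equal(cor$stage, "corrected")
  expect_error(distance_correction(cor, d), "already corrected")
})

test_that("Otsu matches exhaustive search on bimodal and random samples", {
  set.seed(8)
  v <- c(rnorm(500, 0.1, 0.02), rnorm(500, 0.9, 0.02))
  th <- otsu_threshold(v)
  expect_gt(th, 0.3)
  expect_lt(th, 0.7)
  expect_equal(th, oracle_otsu(v), tolerance = 1e-9)
  for (s in 1:5) {
    set.seed(s)
    u <- runif(200)^2
    expect_equal(otsu_threshold(u), oracle_otsu(u), tolerance = 1e-9)
  }
})

test_that("Otsu edge cases behave deterministically", {
  v <- rep(c(0.2, 0.8), each = 50)
  th <- otsu_threshold(v)
  expect_gt(th, 0.2)
  expect_lt(th, 0.8)
  # duplicating the sample leaves the threshold unchanged
  expect_equal(otsu_threshold(c(v, v)), th)
  expect_error(otsu_threshold(rep(0.5, 10)), "constant")
})

test_that("predicted labels recover the high mode of a bimodal map", {
  dm <- c(9, 9, 9)
  peri <- sphere_mask(dm, c(5, 5, 5), 4)
  n <- sum(peri$data)
  set.seed(12)
  hi <- rbinom(n, 1, 0.3)
  scores <- ifelse(hi == 1, rnorm(n, 0.85, 0.03), rnorm(n, 0.15, 0.03))
  scores <- pmin(pmax(scores, 0), 1)
  cor <- probability_map(scores, peri, stage = "corrected")
  pl <- predicted_labels(cor)
  expect_equal(as.integer(pl$mask$data[peri$data == 1L]), hi)
  expect_gt(pl$threshold, 0.25)
  expect_lt(pl$threshold, 0.75)

  flat <- probability_map(rep(0.4, n), peri, stage = "corrected")
  expect_error(predicted_labels(flat), "constant")
})

test_that("thresholding is monotone in the scores", {
  dm <- c(7, 7, 7)
  peri <- sphere_mask(dm, c(4, 4, 4), 3)
  n <- sum(peri$data)
  set.seed(3)
  s <- runif(n)
  cor <- probability_map(s, peri, stage = "corrected")
  pl <- predicted_labels(cor)
  inmask <- as.integer(pl$mask$data[peri$data == 1L])
  s2 <- ifelse(inmask == 1L, pmin(1, s + 0.05), pmax(0, s - 0.05))
  keep <- s2 > pl$threshold
  expect_true(all(keep[inmask == 1L]))
})
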