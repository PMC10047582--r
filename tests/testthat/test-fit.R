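make_blobs <- function(n_per_class, d = 3, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c(0, 1), each = n_per_class))
}

test_that("undersampling keeps all minority rows and balances exactly", {
  y <- rep(c(1L, 0L), c(20, 100))
  idx <- undersample(y, seed = 3)
  expect_equal(length(idx), 40)
  expect_true(all(which(y == 1L) %in% idx))
  expect_equal(sum(y[idx] == 0L), 20)

  # balanced input is kept untouched
  yb <- rep(c(0L, 1L), 30)
  expect_identical(undersample(yb, seed = 1), seq_along(yb))

  # deterministic per seed, different across seeds
  expect_identical(undersample(y, seed = 7), undersample(y, seed = 7))
  expect_false(identical(undersample(y, seed = 7), undersample(y, seed = 8)))
  expect_equal(length(undersample(y, seed = 8)), 40)

  expect_error(undersample(rep(1L, 10)), "nonempty")
})

test_that("all four backends separate well-separated blobs perfectly", {
  bl <- make_blobs(150, sep = 10)
  for (alg in c("catboost", "xgboost", "random_forest", "lightgbm")) {
    m <- recur_fit(bl$x, bl$y, algorithm = alg, seed = 2)
    p <- predict(m, bl$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(auc_score(p, bl$y), 1, tolerance = 1e-9,
                 info = alg)
  }
})

test_that("randomly permuted labels give chance-level held-out AUC", {
  aucs <- sapply(1:10, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(600 * 5), ncol = 5)
    y <- rep(c(0, 1), each = 300)[sample(600)]
    tr <- sample(600, 400)
    m <- recur_fit(x[tr, ], y[tr], "catboost", seed = s,
                   hyperparams = list(nrounds = 30))
    auc_score(predict(m, x[-tr, ]), y[-tr])
  })
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("training is seed-deterministic for the boosting backends", {
  bl <- make_blobs(80, sep = 2, seed = 5)
  for (alg in c("catboost", "xgboost", "lightgbm")) {
    m1 <- recur_fit(bl$x, bl$y, alg, seed = 11)
    m2 <- recur_fit(bl$x, bl$y, alg, seed = 11)
    expect_identical(predict(m1, bl$x), predict(m2, bl$x), info = alg)
  }
})

test_that("an informative feature dominates the importance ranking", {
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    x <- matrix(rnorm(n * 10), ncol = 10)
    colnames(x) <- paste0("f", 1:10)
    y <- as.numeric(x[, 1] + rnorm(n, sd = 0.3) > 0)
    m <- recur_fit(x, y, "catboost", seed = s,
                   hyperparams = list(nrounds = 30))
    feature_importance(m)$ranking$feature[1] == "f1"
  })
  expect_gte(sum(hits), 9)
})

test_that("importances normalize to one and ignore column order", {
  bl <- make_blobs(100, d = 6, sep = 1, seed = 9)
  m <- recur_fit(bl$x, bl$y, "catboost", seed = 1)
  imp <- feature_importance(m)
  expect_true(all(imp$ranking$importance >= 0))
  expect_equal(imp$ranking$cumulative[nrow(imp$ranking)], 1, tolerance = 1e-9)

  perm <- c(4, 2, 6, 1, 3, 5)
  m2 <- recur_fit(bl$x[, perm], bl$y, "catboost", seed = 1)
  imp2 <- feature_importance(m2)
  r1 <- setNames(imp$ranking$importance, imp$ranking$feature)
  r2 <- setNames(imp2$ranking$importance, imp2$ranking$feature)
  expect_equal(r1[sort(names(r1))], r2[sort(names(r2))], tolerance = 1e-9)
})

test_that("voxel AUC is invariant under strictly monotone score transforms", {
  set.seed(77)
  s <- runif(500)
  y <- rbinom(500, 1, s)
  a1 <- auc_score(s, y)
  expect_equal(auc_score(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y), a1)
  expect_equal(auc_score(s^3, y), a1)
})

test_that("degenerate training inputs are rejected", {
  bl <- make_blobs(50)
  expect_error(recur_fit(bl$x, rep(0, nrow(bl$x)), "catboost"), "class")
  xx <- bl$x
  xx[1, 1] <- NA
  expect_error(recur_fit(xx, bl$y, "catboost"), "finite")
  expect_error(recur_fit(bl$x, bl$y, "boostzilla"), "arg")
})
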