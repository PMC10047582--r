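#' Balance classes by random undersampling
#'
#' Retains every minority-class row plus a uniformly random,
#' seed-deterministic subset of majority rows of the same size, so the
#' result has exactly `2 x` the minority count.  Undersampling is pooled
#' across cases: feed it the concatenated labels of the whole training
#' cohort.
#'
#' @param labels vector of 0/1 class labels (both classes nonempty).
#' @param seed RNG seed for the majority subset.
#' @return sorted integer indices of retained rows.
#' @examples
#' idx <- undersample(rep(c(1, 0), c(20, 100)), seed = 1)
#' length(idx)  # 40
#' @export
undersample <- function(labels, seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be nonempty")
  if (n1 == n0) return(seq_along(labels))
  minority <- if (n1 <= n0) 1L else 0L
  keep_min <- which(labels == minority)
  maj <- which(labels != minority)
  keep_maj <- with_seed(seed, sample(maj, length(keep_min)))
  sort(c(keep_min, keep_maj))
}

#' Fit a voxelwise recurrence classifier
#'
#' One interface over the four ensemble backends.  Algorithm ids follow
#' the common names of the corresponding boosting flavors:
#' \describe{
#'   \item{`catboost`}{oblivious-tree (symmetric-tree) gradient boosting,
#'     implemented in this package: every level of a tree shares one
#'     split, the tree structure used by categorical boosting.}
#'   \item{`xgboost`}{depth-wise histogram gradient boosting (xgboost
#'     backend).}
#'   \item{`lightgbm`}{leaf-wise (loss-guided) histogram gradient
#'     boosting — the growth policy of the light gradient boosting
#'     machine — run through the xgboost backend.}
#'   \item{`random_forest`}{probability random forest (ranger backend).}
#' }
#' Default hyperparameters are fixed and documented (no tuning); training
#' is single-threaded and seed-deterministic.
#'
#' @param x numeric feature matrix (rows = voxels), typically the balanced
#'   output of [undersample()].
#' @param y 0/1 labels (1 = recurrence).
#' @param algorithm one of `"catboost"`, `"xgboost"`, `"random_forest"`,
#'   `"lightgbm"`.
#' @param hyperparams named list overriding backend defaults
#'   (`nrounds`/`num.trees`, `depth`/`max_depth`, `eta`, `lambda`, ...).
#' @param seed RNG seed passed to the backend.
#' @return an object of class `recur_model` with `print()`, `summary()`,
#'   `predict()` and `plot()` methods.
#' @seealso [feature_importance()], [predict.recur_model()]
#' @export
recur_fit <- function(x, y, algorithm = c("catboost", "xgboost",
                                          "random_forest", "lightgbm"),
                      hyperparams = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), all(y %in% c(0, 1)))
  if (sum(y == 1) < 2L || sum(y == 0) < 2L)
    stop("need at least 2 rows per class")
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))

  hp <- function(name, default) {
    if (!is.null(hyperparams[[name]])) hyperparams[[name]] else default
  }

  fit <- switch(algorithm,
    catboost = {
      nrounds <- hp("nrounds", 100L)
      depth <- hp("depth", 6L)
      eta <- hp("eta", 0.1)
      lambda <- hp("lambda", 1.0)
      n_bins <- hp("n_bins", 64L)
      mod <- cpp_oblivious_train(x, y, as.integer(nrounds),
                                 as.integer(depth), eta, lambda,
                                 as.integer(n_bins))
      list(backend = "oblivious", model = mod,
           params = list(nrounds = nrounds, depth = depth, eta = eta,
                         lambda = lambda, n_bins = n_bins))
    },
    xgboost = ,
    lightgbm = {
      params <- list(objective = "binary:logistic", tree_method = "hist",
                     eta = hp("eta", 0.1), nthread = 1L,
                     seed = as.integer(seed),
                     lambda = hp("lambda", 1.0))
      if (algorithm == "lightgbm") {
        params$grow_policy <- "lossguide"
        params$max_leaves <- hp("max_leaves", 31L)
        params$max_depth <- hp("max_depth", 0L)
      } else {
        params$max_depth <- hp("max_depth", 6L)
      }
      nrounds <- hp("nrounds", 100L)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1L)
      mod <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
      list(backend = "xgboost", model = mod,
           params = c(params, nrounds = nrounds))
    },
    random_forest = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x,
                       check.names = FALSE)
      mod <- ranger::ranger(.y ~ ., data = df,
                            num.trees = hp("num.trees", 200L),
                            probability = TRUE, seed = seed,
                            num.threads = 1L, importance = "impurity",
                            respect.unordered.factors = "order")
      list(backend = "ranger", model = mod,
           params = list(num.trees = hp("num.trees", 200L)))
    })

  structure(list(algorithm = algorithm, backend = fit$backend,
                 model = fit$model, hyperparams = fit$params,
                 feature_names = colnames(x), seed = seed,
                 n_train = nrow(x),
                 class_counts = c(nonrecurrence = sum(y == 0),
                                  recurrence = sum(y == 1))),
            class = "recur_model")
}

#' Predict recurrence probabilities
#'
#' @param object a [recur_fit()] model.
#' @param newdata feature matrix with the training columns (matched by
#'   name when present).
#' @param ... unused.
#' @return numeric vector of recurrence-class probabilities in `[0, 1]`.
#' @export
predict.recur_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && all(object$feature_names %in% colnames(x)))
    x <- x[, object$feature_names, drop = FALSE]
  p <- switch(object$backend,
    oblivious = cpp_oblivious_predict(x, object$model$bias, object$model$feat,
                                      object$model$thr, object$model$leaves),
    xgboost = predict(object$model, xgboost::xgb.DMatrix(x, nthread = 1L)),
    ranger = {
      df <- data.frame(x, check.names = FALSE)
      pr <- predict(object$model, data = df, num.threads = 1L)$predictions
      pr[, "1"]
    })
  pmin(1, pmax(0, as.numeric(p)))
}

#' @export
print.recur_model <- function(x, ...) {
  cat(sprintf("<recur_model> %s (%s backend), %d training voxels (%d/%d per class), %d features\n",
              x$algorithm, x$backend, x$n_train,
              x$class_counts[["recurrence"]], x$class_counts[["nonrecurrence"]],
              length(x$feature_names)))
  invisible(x)
}

#' @export
summary.recur_model <- function(object, ...) {
  print(object)
  imp <- feature_importance(object)
  cat("Top features by importance:\n")
  print(head(imp$ranking, 5L), row.names = FALSE)
  invisible(object)
}

#' Feature importance ranking
#'
#' Normalized (summing to 1) importances of a fitted model, ordered
#' decreasing, with the cumulative-importance curve.  Backends report
#' split-gain (boosting) or impurity-decrease (random forest) importances;
#' both are non-negative.
#'
#' @param model a [recur_fit()] model.
#' @return an object of class `recur_importance`: list with `ranking`
#'   (data.frame `feature`, `importance`, `cumulative`) and `algorithm`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "recur_model"))
  raw <- switch(model$backend,
    oblivious = setNames(as.numeric(model$model$gain), model$feature_names),
    xgboost = {
      imp <- xgboost::xgb.importance(model = model$model)
      v <- setNames(rep(0, length(model$feature_names)), model$feature_names)
      v[imp$Feature] <- imp$Gain
      v
    },
    ranger = {
      v <- model$model$variable.importance
      v[model$feature_names]
    })
  if (is.null(raw)) stop(sprintf("backend '%s' reports no importances", model$backend))
  raw <- pmax(raw, 0)
  tot <- sum(raw)
  imp <- if (tot > 0) raw / tot else rep(1 / length(raw), length(raw))
  ord <- order(imp, decreasing = TRUE)
  ranking <- data.frame(feature = names(imp)[ord], importance = imp[ord],
                        cumulative = cumsum(imp[ord]),
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ranking = ranking, algorithm = model$algorithm),
            class = "recur_importance")
}

#' @export
print.recur_importance <- function(x, ...) {
  cat(sprintf("<recur_importance> %s, %d features\n", x$algorithm,
              nrow(x$ranking)))
  print(head(x$ranking, 10L), row.names = FALSE)
  invisible(x)
}

#' @rdname feature_importance
#' @param x a `recur_importance`.
#' @param top_n number of features shown in the ranking panel.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.recur_importance <- function(x, top_n = 20L, ...) {
  r <- x$ranking
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  k <- min(top_n, nrow(r))
  graphics::barplot(rev(r$importance[seq_len(k)]),
                    names.arg = rev(r$feature[seq_len(k)]), horiz = TRUE,
                    las = 1, cex.names = 0.6,
                    main = sprintf("%s importance", x$algorithm),
                    xlab = "normalized importance", ...)
  graphics::par(mar = c(4, 4, 2, 1))
  plot(seq_len(nrow(r)), r$cumulative, type = "l",
       xlab = "number of features", ylab = "cumulative importance",
       main = "cumulative importance", ylim = c(0, 1))
  graphics::abline(h = 0.95, lty = 2)
  invisible(x)
}

#' @rdname feature_importance
#' @export
plot.recur_model <- function(x, ...) plot(feature_importance(x), ...)
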