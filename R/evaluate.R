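#' Rank-based AUC
#'
#' Area under the ROC curve computed from midranks (equivalent to the
#' Wilcoxon statistic), invariant under any strictly increasing transform
#' of the scores.
#'
#' @param scores numeric scores, higher = more recurrence-like.
#' @param truth 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` with a `reason` attribute when the
#'   truth has a single class.
#' @export
auc_score <- function(scores, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "single-class ground truth"
    return(out)
  }
  r <- rank(scores)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_metrics <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  tp <- sum(truth == 1L & pred == 1L)
  fp <- sum(truth == 0L & pred == 1L)
  fn <- sum(truth == 1L & pred == 0L)
  tn <- sum(truth == 0L & pred == 0L)
  n <- tp + fp + fn + tn
  precision_flag <- (tp + fp) == 0L
  precision <- if (precision_flag) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall <= 0) 0 else
    2 * precision * recall / (precision + recall)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  list(accuracy = po, precision = precision, recall = recall, f1 = f1,
       kappa = kappa, precision_flag = precision_flag,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Voxelwise evaluation metrics
#'
#' Compares predictions with ground truth voxel by voxel over the
#' peritumoral support: AUC from the continuous scores, the remaining
#' metrics from the thresholded labels.  Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)`; the positive class is recurrence, and an
#' undefined precision (no positive predictions) is reported as 0 with a
#' flag.
#'
#' @param scores [probability_map()] or numeric vector over the support.
#' @param predicted predicted [mask_volume] (or 0/1 vector).
#' @param truth a [derive_labels()] `label_volume`.
#' @param case_id identifier carried into the report row.
#' @return one-row data.frame: `case_id`, `mode`, `auc`, `accuracy`,
#'   `precision`, `recall`, `f1`, `kappa`, plus bookkeeping flags.
#' @export
voxel_metrics <- function(scores, predicted, truth, case_id = "case") {
  stopifnot(inherits(truth, "label_volume"))
  sel <- truth$data != 255L
  y <- as.integer(truth$data[sel])
  s <- if (inherits(scores, "probability_map")) map_values(scores)
       else as.numeric(scores)
  p <- if (inherits(predicted, "mask_volume")) as.integer(predicted$data[sel])
       else as.integer(predicted)
  stopifnot(length(s) == length(y), length(p) == length(y))
  auc <- auc_score(s, y)
  bm <- binary_metrics(y, p)
  data.frame(case_id = case_id, mode = "voxel", auc = as.numeric(auc),
             accuracy = bm$accuracy, precision = bm$precision,
             recall = bm$recall, f1 = bm$f1, kappa = bm$kappa,
             auc_reason = if (is.na(auc)) attr(auc, "reason") else "",
             precision_flag = bm$precision_flag,
             stringsAsFactors = FALSE)
}

sector_axis_labels <- function(axes) {
  lab <- list(R = c("right", "left"), L = c("left", "right"),
              A = c("anterior", "posterior"), P = c("posterior", "anterior"),
              S = c("superior", "inferior"), I = c("inferior", "superior"))
  lapply(axes, function(a) lab[[a]])
}

#' Cavity-centered sector partition of the peritumor
#'
#' Divides the peritumoral region into directional sectors around the
#' cavity centroid: the unit displacement of each voxel is classified per
#' anatomical axis as negative / neutral / positive using an angular
#' neutral band (default +-22.5 degrees about the plane through the
#' centroid), and the resulting sign triple indexes one of 26 sectors —
#' 6 faces (anterior, posterior, superior, inferior, right, left), 12
#' edges and 8 corners.  The all-neutral triple cannot occur for a
#' nonzero displacement; a voxel exactly at the centroid is assigned to
#' its largest-displacement axis (positive side of axis 1 when truly
#' zero).
#'
#' @param peritumor nonempty [mask_volume].
#' @param cavity nonempty [mask_volume]; its world centroid is the
#'   reference point.
#' @param neutral_band_deg half-width of the angular neutral band per
#'   axis.
#' @return an object of class `sector_partition`: list with `sector`
#'   (3D integer array, 0 outside the peritumor), `ids` (per-voxel sector
#'   id over the support), `catalog` (data.frame `id`, `name`, the sign
#'   triple and voxel `size`), `centroid_mm`.
#' @export
sector_partition <- function(peritumor, cavity, neutral_band_deg = 22.5) {
  stopifnot(inherits(peritumor, "mask_volume"), inherits(cavity, "mask_volume"))
  check_same_geometry(peritumor, cavity, "masks")
  if (mask_count(peritumor) == 0L) stop("empty peritumor mask")
  if (mask_count(cavity) == 0L) stop("empty cavity mask")
  dm <- dim(peritumor$data)
  sp <- peritumor$spacing
  ci <- arrayInd(which(cavity$data != 0L), dm)
  centroid <- (colMeans(ci) - 1) * sp
  vi <- which(peritumor$data != 0L)
  ai <- arrayInd(vi, dm)
  disp <- sweep(sweep(ai, 2L, c(1, 1, 1), "-") %*% diag(sp), 2L, centroid, "-")
  nrm <- sqrt(rowSums(disp^2))
  zero <- nrm < 1e-9
  cosc <- disp / pmax(nrm, 1e-9)
  thr <- sin(neutral_band_deg * pi / 180)
  sgn <- sign(cosc) * (abs(cosc) >= thr)
  if (any(zero)) sgn[zero, ] <- 0
  # safety net: a voxel at (or numerically at) the centroid takes its
  # largest-displacement axis, positive axis 1 if truly zero
  allz <- rowSums(sgn != 0) == 0L
  if (any(allz)) {
    for (k in which(allz)) {
      a <- which.max(abs(disp[k, ]))
      sgn[k, a] <- if (disp[k, a] >= 0) 1 else -1
    }
  }
  ids <- (sgn[, 1L] + 1) * 9 + (sgn[, 2L] + 1) * 3 + (sgn[, 3L] + 1) + 1

  axlab <- sector_axis_labels(peritumor$axes)
  triples <- expand.grid(s3 = -1:1, s2 = -1:1, s1 = -1:1)[, 3:1]
  triples <- triples[!(triples$s1 == 0 & triples$s2 == 0 & triples$s3 == 0), ]
  name_of <- function(s) {
    parts <- character()
    for (a in 1:3) {
      if (s[a] == 1) parts <- c(parts, axlab[[a]][1L])
      else if (s[a] == -1) parts <- c(parts, axlab[[a]][2L])
    }
    # anatomical reading order: AP, SI, RL
    pri <- c(anterior = 1, posterior = 1, superior = 2, inferior = 2,
             right = 3, left = 3)
    paste(parts[order(pri[parts])], collapse = "-")
  }
  catalog <- data.frame(id = (triples$s1 + 1) * 9 + (triples$s2 + 1) * 3 +
                          (triples$s3 + 1) + 1,
                        name = apply(triples, 1L, name_of),
                        s1 = triples$s1, s2 = triples$s2, s3 = triples$s3,
                        stringsAsFactors = FALSE)
  catalog$size <- as.integer(tabulate(match(ids, catalog$id),
                                      nbins = nrow(catalog)))
  sec <- array(0L, dm)
  sec[vi] <- as.integer(ids)
  structure(list(sector = sec, ids = as.integer(ids), catalog = catalog,
                 centroid_mm = centroid, voxel_index = vi),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat(sprintf("<sector_partition> %d voxels over %d populated sectors (of 26)\n",
              length(x$ids), sum(x$catalog$size > 0)))
  invisible(x)
}

#' Per-sector binary labels
#'
#' A sector is positive when the positive voxels inside it reach
#' `activation_fraction` of its peritumoral voxel count (>=, default 1%).
#' The same rule is applied to ground truth and to predictions.  Empty
#' sectors are excluded (reported in the `excluded` attribute).
#'
#' @param partition a [sector_partition()].
#' @param voxel_mask [mask_volume] (or 0/1 vector over the support) of
#'   positive voxels.
#' @param activation_fraction activation threshold as a fraction of sector
#'   size.
#' @return named logical vector over populated sectors (names = sector
#'   names).
#' @export
sector_labels <- function(partition, voxel_mask, activation_fraction = 0.01) {
  stopifnot(inherits(partition, "sector_partition"))
  v <- if (inherits(voxel_mask, "mask_volume"))
    as.integer(voxel_mask$data[partition$voxel_index]) else as.integer(voxel_mask)
  stopifnot(length(v) == length(partition$ids))
  cat_ <- partition$catalog
  pos <- tapply(v, factor(partition$ids, levels = cat_$id), sum)
  pos[is.na(pos)] <- 0
  keep <- cat_$size > 0L
  out <- as.vector(pos[keep]) >= activation_fraction * cat_$size[keep]
  names(out) <- cat_$name[keep]
  attr(out, "excluded") <- cat_$name[!keep]
  out
}

#' Sector (region-based) evaluation metrics
#'
#' Scores predictions by directional sectors instead of voxels: ground
#' truth and predicted masks are reduced to per-sector binaries with
#' [sector_labels()], the threshold metrics are computed over sectors, and
#' the sector AUC uses a continuous per-sector score — by default the 95th
#' percentile of the corrected voxel probabilities inside the sector
#' (configurable to max or mean; max is fragile to single-voxel noise and
#' mean dilutes focal signals).
#'
#' @param partition a [sector_partition()].
#' @param truth `label_volume` (or recurrence [mask_volume]) of ground
#'   truth.
#' @param predicted predicted [mask_volume].
#' @param corrected corrected-stage [probability_map()] supplying sector
#'   scores.
#' @param activation_fraction see [sector_labels()].
#' @param score_stat `"p95"`, `"max"` or `"mean"`.
#' @param case_id identifier carried into the report row.
#' @return one-row data.frame as in [voxel_metrics()], `mode = "sector"`.
#' @export
sector_metrics <- function(partition, truth, predicted, corrected,
                           activation_fraction = 0.01,
                           score_stat = c("p95", "max", "mean"),
                           case_id = "case") {
  score_stat <- match.arg(score_stat)
  stopifnot(inherits(partition, "sector_partition"))
  tv <- if (inherits(truth, "label_volume"))
    as.integer(truth$data[partition$voxel_index] == 1L)
  else as.integer(truth$data[partition$voxel_index])
  t_sec <- sector_labels(partition, tv, activation_fraction)
  p_sec <- sector_labels(partition, predicted, activation_fraction)
  pv <- map_values_on(corrected, partition$voxel_index)
  f <- factor(partition$ids,
              levels = partition$catalog$id[partition$catalog$size > 0L])
  s_sec <- tapply(pv, f, function(v) switch(score_stat,
                                            p95 = quantile(v, 0.95, names = FALSE),
                                            max = max(v), mean = mean(v)))
  if (length(t_sec) < 2L) stop("need at least 2 populated sectors")
  auc <- auc_score(as.numeric(s_sec), as.integer(t_sec))
  bm <- binary_metrics(as.integer(t_sec), as.integer(p_sec))
  data.frame(case_id = case_id, mode = "sector", auc = as.numeric(auc),
             accuracy = bm$accuracy, precision = bm$precision,
             recall = bm$recall, f1 = bm$f1, kappa = bm$kappa,
             auc_reason = if (is.na(auc)) attr(auc, "reason") else "",
             precision_flag = bm$precision_flag,
             stringsAsFactors = FALSE)
}

map_values_on <- function(map, voxel_index) {
  stopifnot(inherits(map, "probability_map"))
  map$data[voxel_index]
}

#' Aggregate per-case metrics into a cohort summary
#'
#' Mean and standard deviation (population convention) per metric and
#' evaluation mode, with a `mean ± SD` formatted column.  Cases with a
#' missing metric (e.g. AUC undefined under single-class truth) are
#' excluded from that metric's aggregate and counted in `n_missing`.
#'
#' @param per_case data.frame of per-case rows from [voxel_metrics()] /
#'   [sector_metrics()] (rbind several cases and modes freely), with an
#'   optional `algorithm` column.
#' @return data.frame with one row per (algorithm,) mode and metric:
#'   `mean`, `sd`, `n`, `n_missing`, `formatted`.
#' @export
aggregate_cohort <- function(per_case) {
  stopifnot(nrow(per_case) >= 1L)
  metrics <- c("auc", "accuracy", "precision", "recall", "f1", "kappa")
  keys <- intersect(c("algorithm", "mode"), names(per_case))
  split_keys <- interaction(per_case[keys], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(per_case, split_keys), function(d) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]]
      ok <- is.finite(v)
      mu <- mean(v[ok])
      sdv <- sqrt(mean((v[ok] - mu)^2))
      row <- d[1L, keys, drop = FALSE]
      cbind(row,
            data.frame(metric = m, mean = mu, sd = sdv, n = sum(ok),
                       n_missing = sum(!ok),
                       formatted = sprintf("%.2f ± %.2f", mu, sdv),
                       stringsAsFactors = FALSE))
    }))
  }))
  rownames(out) <- NULL
  out
}
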