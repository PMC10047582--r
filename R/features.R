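#' Feature families and manifest
#'
#' Feature definitions follow the Image Biomarker Standardisation
#' Initiative: 19 first-order statistics plus 75 texture features split
#' over five matrix families (GLCM 24, GLRLM 16, GLSZM 16, NGTDM 5,
#' GLDM 14).  A manifest names every column of a feature table as
#' `modality_filter_family_feature`.
#'
#' Conventions, chosen once and fixed: grey levels are equal-width bins
#' within the local kernel range; GLCM and GLRLM aggregate by averaging
#' features over the 13 unique distance-1 directions; GLSZM zones and the
#' NGTDM/GLDM neighbourhoods use 26-connectivity; the GLDM dependence of a
#' voxel is 1 (the centre) plus the number of neighbours whose level
#' differs by at most `alpha = 0`; percentiles interpolate linearly
#' between order statistics.
#'
#' @param family one of `"firstorder"`, `"glcm"`, `"glrlm"`, `"glszm"`,
#'   `"ngtdm"`, `"gldm"`.
#' @return `feature_names()` returns the ordered feature names of one
#'   family.
#' @export
feature_names <- function(family) {
  switch(family,
    firstorder = c("energy", "total_energy", "entropy", "minimum", "p10",
                   "p90", "maximum", "mean", "median", "iqr", "range",
                   "mad", "rmad", "rms", "stddev", "skewness", "kurtosis",
                   "variance", "uniformity"),
    glcm = c("autocorrelation", "joint_average", "cluster_prominence",
             "cluster_shade", "cluster_tendency", "contrast", "correlation",
             "difference_average", "difference_entropy",
             "difference_variance", "joint_energy", "joint_entropy",
             "imc1", "imc2", "idm", "idmn", "id", "idn",
             "inverse_variance", "maximum_probability", "sum_average",
             "sum_entropy", "sum_squares", "mcc"),
    glrlm = c("sre", "lre", "gln", "glnn", "rln", "rlnn", "rp", "glv",
              "rv", "re", "lglre", "hglre", "srlgle", "srhgle", "lrlgle",
              "lrhgle"),
    glszm = c("sae", "lae", "gln", "glnn", "szn", "sznn", "zp", "glv",
              "zv", "ze", "lglze", "hglze", "salgle", "sahgle", "lalgle",
              "lahgle"),
    ngtdm = c("coarseness", "contrast", "busyness", "complexity",
              "strength"),
    gldm = c("sde", "lde", "gln", "dn", "dnn", "glv", "dv", "de", "lgle",
             "hgle", "sdlgle", "sdhgle", "ldlgle", "ldhgle"),
    stop(sprintf("unknown feature family '%s'", family))
  )
}

all_families <- function() c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm")

#' Equal-width grey-level discretization
#'
#' Maps values to integer levels `1..n_bins` over equal-width bins spanning
#' the value range; constant input maps to level 1.
#'
#' @param values finite numeric vector (or array).
#' @param n_bins number of levels (>= 2).
#' @return integer levels with the shape of the input.
#' @examples
#' discretize(c(0, 1, 2, 3), 2)  # 1 1 2 2
#' @export
discretize <- function(values, n_bins = 16L) {
  if (n_bins < 2L) stop("n_bins must be at least 2")
  if (any(!is.finite(values))) stop("values must be finite")
  mn <- min(values)
  mx <- max(values)
  if (mx <= mn) {
    lev <- rep(1L, length(values))
  } else {
    w <- (mx - mn) / n_bins
    lev <- pmin(as.integer(floor((values - mn) / w)) + 1L, as.integer(n_bins))
  }
  if (!is.null(dim(values))) dim(lev) <- dim(values)
  lev
}

#' First-order statistical features
#'
#' The 19 first-order features of a value vector, computed on the raw
#' (undiscretized) values except entropy and uniformity, which use the
#' equal-width discretized histogram.  Standard deviation, variance,
#' skewness and kurtosis use the population (1/n) convention; kurtosis is
#' not excess-corrected; a single value (or zero variance) yields skewness
#' and kurtosis 0.
#'
#' @param values numeric vector, at least one value.
#' @param n_bins discretization bins for entropy/uniformity.
#' @param voxel_volume_mm3 voxel volume used by total energy.
#' @return named numeric vector of length 19.
#' @examples
#' first_order_features(c(1, 2, 3, 4))[c("mean", "variance", "range")]
#' @export
first_order_features <- function(values, n_bins = 16L, voxel_volume_mm3 = 1) {
  if (length(values) < 1L) stop("need at least one value")
  out <- cpp_first_order(as.numeric(values), as.integer(n_bins),
                         voxel_volume_mm3)
  names(out) <- feature_names("firstorder")
  out
}

#' Texture matrices
#'
#' Builds the raw (count) texture matrix of one family for an integer
#' level patch.  GLCM returns an `L x L x 13` array (symmetric counts, one
#' slice per direction); GLRLM an `L x Jmax x 13` run-length array; GLSZM
#' an `L x Smax` size-zone matrix (26-connected zones); NGTDM an `L x 2`
#' matrix of per-level counts `n_i` and summed absolute neighbourhood
#' differences `s_i`; GLDM an `L x 27` dependence matrix.
#'
#' @param levels integer 3D array with values in `1..n_bins` (see
#'   [discretize()]).
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`,
#'   `"gldm"`.
#' @param n_bins number of grey levels L.
#' @param validity optional logical/0-1 array marking voxels that belong to
#'   the patch support; invalid voxels break runs and zones and are
#'   excluded from neighbourhoods.
#' @param alpha GLDM dependence tolerance on the level difference.
#' @return the family matrix with attributes `family`, `n_bins` and
#'   `n_valid` (number of support voxels).
#' @export
texture_matrix <- function(levels, family, n_bins = max(levels),
                           validity = NULL, alpha = 0L) {
  family <- match.arg(tolower(family), all_families()[-1L])
  if (!is.array(levels) || length(dim(levels)) != 3L)
    stop("levels must be a 3D array")
  dm <- dim(levels)
  if (is.null(validity)) validity <- array(1L, dm)
  valid <- array(as.integer(validity != 0), dm)
  lv <- array(as.integer(levels), dm)
  if (any(lv[valid == 1L] < 1L) || any(lv[valid == 1L] > n_bins))
    stop("levels must lie in 1..n_bins")
  L <- as.integer(n_bins)
  m <- switch(family,
    glcm = cpp_glcm(lv, dm, valid, L),
    glrlm = cpp_glrlm(lv, dm, valid, L),
    glszm = cpp_glszm(lv, dm, valid, L),
    ngtdm = cpp_ngtdm(lv, dm, valid, L),
    gldm = cpp_gldm(lv, dm, valid, L, as.integer(alpha)))
  attr(m, "family") <- family
  attr(m, "n_bins") <- L
  attr(m, "n_valid") <- sum(valid)
  m
}

EPS <- 2.220446e-16

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_features_one <- function(p, iv, Ng) {
  px <- rowSums(p)                       # symmetric: px == py
  I <- matrix(iv, length(iv), length(iv))
  J <- t(I)
  mux <- sum(iv * px)
  sigx <- sqrt(sum((iv - mux)^2 * px))
  ks <- as.numeric(names(ps <- tapply(p, I + J, sum)))
  kd <- as.numeric(names(pd <- tapply(p, abs(I - J), sum)))
  ps <- as.numeric(ps)
  pd <- as.numeric(pd)
  da <- sum(kd * pd)
  hxy <- -sum(xlog2(p))
  hx <- -sum(xlog2(px))
  pxy <- px %o% px
  hxy1 <- -sum(p * log2(pxy + EPS))
  hxy2 <- -sum(xlog2(pxy))
  corr <- if (sigx < 1e-12) 1 else (sum(I * J * p) - mux^2) / sigx^2
  mcc <- if (length(iv) == 1L) 1 else {
    A <- p / px
    B <- sweep(p, 2L, px, "/")
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(0, min(1, ev[2L])))
  }
  c(autocorrelation = sum(I * J * p),
    joint_average = mux,
    cluster_prominence = sum((I + J - 2 * mux)^4 * p),
    cluster_shade = sum((I + J - 2 * mux)^3 * p),
    cluster_tendency = sum((I + J - 2 * mux)^2 * p),
    contrast = sum((I - J)^2 * p),
    correlation = corr,
    difference_average = da,
    difference_entropy = -sum(xlog2(pd)),
    difference_variance = sum((kd - da)^2 * pd),
    joint_energy = sum(p^2),
    joint_entropy = hxy,
    imc1 = if (hx < 1e-12) 0 else (hxy - hxy1) / hx,
    imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    idm = sum(p / (1 + (I - J)^2)),
    idmn = sum(p / (1 + ((I - J) / Ng)^2)),
    id = sum(p / (1 + abs(I - J))),
    idn = sum(p / (1 + abs(I - J) / Ng)),
    inverse_variance = sum(p[I != J] / (I - J)[I != J]^2),
    maximum_probability = max(p),
    sum_average = sum(ks * ps),
    sum_entropy = -sum(xlog2(ps)),
    sum_squares = sum((I - mux)^2 * p),
    mcc = mcc)
}

rl_features_one <- function(Rm, Nv, prefix) {
  Nr <- sum(Rm)
  iv <- seq_len(nrow(Rm))
  jv <- seq_len(ncol(Rm))
  p <- Rm / Nr
  I <- matrix(iv, nrow(Rm), ncol(Rm))
  J <- matrix(jv, nrow(Rm), ncol(Rm), byrow = TRUE)
  mu_i <- sum(I * p)
  mu_j <- sum(J * p)
  v <- c(sum(p / J^2),
         sum(p * J^2),
         sum(rowSums(Rm)^2) / Nr,
         sum(rowSums(Rm)^2) / Nr^2,
         sum(colSums(Rm)^2) / Nr,
         sum(colSums(Rm)^2) / Nr^2,
         Nr / Nv,
         sum((I - mu_i)^2 * p),
         sum((J - mu_j)^2 * p),
         -sum(xlog2(p)),
         sum(p / I^2),
         sum(p * I^2),
         sum(p / (I^2 * J^2)),
         sum(p * I^2 / J^2),
         sum(p * J^2 / I^2),
         sum(p * I^2 * J^2))
  names(v) <- feature_names(prefix)
  v
}

ngtdm_features_one <- function(M) {
  n_i <- M[, 1L]
  s_i <- M[, 2L]
  Nvp <- sum(n_i)
  pres <- which(n_i > 0)
  iv <- pres
  p <- n_i[pres] / Nvp
  s <- s_i[pres]
  Ngp <- length(pres)
  ps <- sum(p * s)
  coarseness <- if (ps <= 0) 1e6 else 1 / ps
  contrast <- if (Ngp <= 1L) 0 else {
    sum(outer(p, p) * outer(iv, iv, "-")^2) / (Ngp * (Ngp - 1)) *
      sum(s) / Nvp
  }
  den_b <- sum(abs(outer(iv * p, iv * p, "-")))
  busyness <- if (den_b <= 0) 0 else ps / den_b
  complexity <- sum(abs(outer(iv, iv, "-")) *
                      (outer(p * s, p * s, "+")) / outer(p, p, "+")) / Nvp
  strength <- if (sum(s) <= 0) 0 else
    sum(outer(p, p, "+") * outer(iv, iv, "-")^2) / sum(s)
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

gldm_features_one <- function(D, Nv) {
  Nz <- sum(D)
  iv <- seq_len(nrow(D))
  jv <- seq_len(ncol(D))
  p <- D / Nz
  I <- matrix(iv, nrow(D), ncol(D))
  J <- matrix(jv, nrow(D), ncol(D), byrow = TRUE)
  mu_i <- sum(I * p)
  mu_j <- sum(J * p)
  v <- c(sum(p / J^2),
         sum(p * J^2),
         sum(rowSums(D)^2) / Nz,
         sum(colSums(D)^2) / Nz,
         sum(colSums(D)^2) / Nz^2,
         sum((I - mu_i)^2 * p),
         sum((J - mu_j)^2 * p),
         -sum(xlog2(p)),
         sum(p / I^2),
         sum(p * I^2),
         sum(p / (I^2 * J^2)),
         sum(p * I^2 / J^2),
         sum(p * J^2 / I^2),
         sum(p * I^2 * J^2))
  names(v) <- feature_names("gldm")
  v
}

#' Texture features from a family matrix
#'
#' Computes the named features of one texture family from a matrix built
#' by [texture_matrix()].  Directional families (GLCM, GLRLM) compute
#' features per direction and average over directions with at least one
#' observation.  Degenerate matrices take their analytic limits (e.g. a
#' single-entry GLCM has joint energy 1, entropy 0, correlation 1), never
#' `NaN`.
#'
#' @param m matrix from [texture_matrix()].
#' @param family family id; defaults to the matrix attribute.
#' @return named numeric vector (24/16/16/5/14 values by family).
#' @export
texture_features <- function(m, family = attr(m, "family")) {
  family <- match.arg(tolower(family), all_families()[-1L])
  Nv <- attr(m, "n_valid")
  if (is.null(Nv)) stop("matrix lacks its n_valid attribute; use texture_matrix()")
  if (family == "glcm") {
    acc <- NULL
    for (d in seq_len(dim(m)[3L])) {
      s <- m[, , d]
      tot <- sum(s)
      if (tot <= 0) next
      pres <- which(rowSums(s) + colSums(s) > 0)
      f <- glcm_features_one(s[pres, pres, drop = FALSE] / tot, pres,
                             length(pres))
      acc <- rbind(acc, f)
    }
    if (is.null(acc)) stop("GLCM has no co-occurrences")
    colMeans(acc)
  } else if (family == "glrlm") {
    acc <- NULL
    for (d in seq_len(dim(m)[3L])) {
      s <- m[, , d]
      if (sum(s) <= 0) next
      acc <- rbind(acc, rl_features_one(s, Nv, "glrlm"))
    }
    if (is.null(acc)) stop("GLRLM has no runs")
    colMeans(acc)
  } else if (family == "glszm") {
    v <- rl_features_one(m, Nv, "glrlm")
    names(v) <- feature_names("glszm")
    v
  } else if (family == "ngtdm") {
    ngtdm_features_one(m)
  } else {
    gldm_features_one(m, Nv)
  }
}

#' Voxelwise feature maps
#'
#' Computes features on a cubic kernel (edge `2r + 1`) centered at every
#' target voxel, intersected with the support mask (e.g. the brain).
#' Kernels with fewer than 8 support voxels are computed on the available
#' voxels and flagged in the QC vector.
#'
#' @param filtered a [voxel_grid] (original or filtered image).
#' @param mask [mask_volume] of target voxels (e.g. the peritumor).
#' @param support optional [mask_volume] restricting kernel membership;
#'   default everything.
#' @param kernel_radius_vox kernel radius r in voxels; r = 0 reduces
#'   first-order maps to the image itself.
#' @param families subset of [all feature families][feature_names].
#' @param n_bins grey levels for discretization.
#' @return list with `features` (voxel x feature matrix, columns
#'   `family_feature`), `qc` (logical flag per voxel) and `voxel_index`
#'   (1-based linear indices into the array).
#' @export
voxelwise_feature_maps <- function(filtered, mask, support = NULL,
                                   kernel_radius_vox = 2L,
                                   families = "firstorder", n_bins = 16L) {
  stopifnot(inherits(filtered, "voxel_grid"), inherits(mask, "mask_volume"))
  check_same_geometry(filtered, mask, "image and mask")
  families <- match.arg(families, all_families(), several.ok = TRUE)
  dm <- dim(filtered$data)
  if (any(2L * kernel_radius_vox + 1L > dm)) stop("kernel larger than grid")
  if (is.null(support)) {
    supp <- array(1L, dm)
  } else {
    check_same_geometry(filtered, support, "image and support")
    supp <- array(as.integer(support$data != 0), dm)
  }
  target <- which(mask$data != 0L)
  if (length(target) == 0L) stop("empty target mask")
  voxvol <- prod(filtered$spacing)
  r <- as.integer(kernel_radius_vox)

  cols <- list()
  qc <- NULL
  if ("firstorder" %in% families) {
    fo <- cpp_voxelwise_firstorder(filtered$data, supp, dm,
                                   as.integer(target - 1L), r,
                                   as.integer(n_bins), voxvol)
    colnames(fo$features) <- paste0("firstorder_", feature_names("firstorder"))
    cols$firstorder <- fo$features
    qc <- fo$qc
  }
  tex_fams <- setdiff(families, "firstorder")
  if (length(tex_fams) > 0L) {
    nt <- length(target)
    mats <- lapply(tex_fams, function(f)
      matrix(NA_real_, nt, length(feature_names(f)),
             dimnames = list(NULL, paste0(f, "_", feature_names(f)))))
    names(mats) <- tex_fams
    if (is.null(qc)) qc <- logical(nt)
    ai <- arrayInd(target, dm)
    for (t in seq_len(nt)) {
      lo <- pmax(ai[t, ] - r, 1L)
      hi <- pmin(ai[t, ] + r, dm)
      patch <- filtered$data[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L],
                             drop = FALSE]
      pv <- supp[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
      nin <- sum(pv)
      if (nin == 0L) {
        pv[ai[t, 1L] - lo[1L] + 1L, ai[t, 2L] - lo[2L] + 1L,
           ai[t, 3L] - lo[3L] + 1L] <- 1L
        nin <- 1L
      }
      qc[t] <- qc[t] | nin < 8L
      lev <- array(1L, dim(patch))
      lev[pv == 1L] <- discretize(patch[pv == 1L], n_bins)
      for (f in tex_fams) {
        m <- texture_matrix(lev, f, n_bins, validity = pv)
        mats[[f]][t, ] <- texture_features(m, f)
      }
    }
    cols <- c(cols, mats)
  }
  features <- do.call(cbind, cols[c(intersect("firstorder", families), tex_fams)])
  list(features = features, qc = qc, voxel_index = target)
}

#' Feature extraction configuration and manifest
#'
#' `feature_config()` fixes the extraction settings; `feature_manifest()`
#' expands it into the ordered column names
#' `modality_filter_family_feature` without computing anything, so any
#' configuration's feature count is explicit up front.
#'
#' @param filters subset of `"original"`, `"log"`, `"wavelet"`, `"lbp"`.
#' @param families feature families, or `"all"`.
#' @param log_sigma_mm Laplacian-of-Gaussian scales in mm.
#' @param kernel_radius kernel radius in voxels (default 2: a 5x5x5
#'   kernel).
#' @param n_bins grey levels for discretization (default 16).
#' @param modalities modality roles expected per case.
#' @return `feature_config()` a `feature_config` object;
#'   `feature_manifest()` a data.frame with columns `name`, `modality`,
#'   `filter`, `family`, `feature`.
#' @export
feature_config <- function(filters = "original", families = "firstorder",
                           log_sigma_mm = c(1, 2, 3), kernel_radius = 2L,
                           n_bins = 16L, modalities = modality_roles()) {
  filters <- match.arg(filters, c("original", "log", "wavelet", "lbp"),
                       several.ok = TRUE)
  if (identical(families, "all")) families <- all_families()
  families <- match.arg(families, all_families(), several.ok = TRUE)
  structure(list(filters = filters, families = families,
                 log_sigma_mm = log_sigma_mm,
                 kernel_radius = as.integer(kernel_radius),
                 n_bins = as.integer(n_bins), modalities = modalities),
            class = "feature_config")
}

filter_ids <- function(config) {
  ids <- character()
  for (f in config$filters) {
    ids <- c(ids, switch(f,
      original = "original",
      log = sprintf("log-sigma-%g-mm", config$log_sigma_mm),
      wavelet = paste0("wavelet-", c("LLL", "HLL", "LHL", "HHL", "LLH",
                                     "HLH", "LHH", "HHH")),
      lbp = "lbp-3D"))
  }
  ids
}

#' @rdname feature_config
#' @param config a `feature_config`.
#' @export
feature_manifest <- function(config) {
  rows <- expand.grid(feature = NA, family = config$families,
                      filter = filter_ids(config),
                      modality = config$modalities,
                      stringsAsFactors = FALSE)[, 4:1]
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    fn <- feature_names(rows$family[i])
    data.frame(modality = rows$modality[i], filter = rows$filter[i],
               family = rows$family[i], feature = fn,
               stringsAsFactors = FALSE)
  }))
  out$name <- with(out, paste(modality, filter, family, feature, sep = "_"))
  stopifnot(!anyDuplicated(out$name))
  out[, c("name", "modality", "filter", "family", "feature")]
}

#' Build the voxel-by-feature table of one case
#'
#' Z-scores every modality within the brain support, applies the filter
#' bank, extracts the configured feature families voxelwise over the
#' peritumoral region, and binds everything into one matrix with the
#' manifest column order.  When the bundle carries a follow-up
#' enhancing-tumor mask, ground-truth labels are attached.
#'
#' @param bundle a `case_bundle` (see [generate_phantom()] /
#'   [read_case_bundle()]).
#' @param config a [feature_config()].
#' @param normalize z-score modalities within the brain mask first
#'   (default `TRUE`).
#' @return an object of class `feature_table`: list with `features`
#'   (matrix, one row per peritumoral voxel), `manifest`, `labels`
#'   (integer vector or `NULL`), `qc`, `voxel_index`, `case_id`, `dim`,
#'   `spacing`.
#' @export
build_feature_table <- function(bundle, config = feature_config(),
                                normalize = TRUE) {
  stopifnot(inherits(bundle, "case_bundle"), inherits(config, "feature_config"))
  missing <- setdiff(config$modalities, names(bundle$modalities))
  if (length(missing) > 0L)
    stop(sprintf("missing modality role(s): %s", paste(missing, collapse = ", ")))
  manifest <- feature_manifest(config)
  support <- bundle$brain_mask
  blocks <- list()
  qc <- NULL
  vidx <- NULL
  for (m in config$modalities) {
    img <- bundle$modalities[[m]]
    if (normalize) img <- zscore_normalize(img, support)
    filt <- apply_filter_bank(img, config$filters, config$log_sigma_mm)
    for (fid in names(filt)) {
      maps <- voxelwise_feature_maps(filt[[fid]], bundle$peritumor_mask,
                                     support = support,
                                     kernel_radius_vox = config$kernel_radius,
                                     families = config$families,
                                     n_bins = config$n_bins)
      colnames(maps$features) <- paste(m, fid, colnames(maps$features), sep = "_")
      blocks[[paste(m, fid, sep = "_")]] <- maps$features
      qc <- if (is.null(qc)) maps$qc else qc | maps$qc
      vidx <- maps$voxel_index
    }
  }
  features <- do.call(cbind, blocks)
  features <- features[, manifest$name, drop = FALSE]
  stopifnot(all(is.finite(features)))
  labels <- NULL
  if (!is.null(bundle$followup_enhancing_mask))
    labels <- label_vector(derive_labels(bundle$peritumor_mask,
                                         bundle$followup_enhancing_mask))
  structure(list(features = features, manifest = manifest, labels = labels,
                 qc = qc, voxel_index = vidx, case_id = bundle$case_id,
                 dim = dim(bundle$peritumor_mask$data),
                 spacing = bundle$peritumor_mask$spacing),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d voxels x %d features%s\n",
              x$case_id, nrow(x$features), ncol(x$features),
              if (is.null(x$labels)) "" else
                sprintf(" (labels: %d recurrence / %d nonrecurrence)",
                        sum(x$labels == 1L), sum(x$labels == 0L))))
  invisible(x)
}
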