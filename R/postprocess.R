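#' Per-voxel recurrence probability map
#'
#' A probability map holds a recurrence score in `[0, 1]` for every voxel
#' of the peritumoral support (NA elsewhere) and a stage flag: `raw`
#' straight from the classifier, `corrected` after the cavity-distance
#' attenuation.
#'
#' @param scores numeric vector of scores, one per peritumoral voxel (in
#'   array index order), or a full 3D array.
#' @param peritumor [mask_volume] defining the support.
#' @param stage `"raw"` or `"corrected"`.
#' @return an object of class `probability_map`: list with `data`
#'   (3D array, NA outside the support), `support`, `stage`, `spacing`.
#' @export
probability_map <- function(scores, peritumor, stage = c("raw", "corrected")) {
  stage <- match.arg(stage)
  stopifnot(inherits(peritumor, "mask_volume"))
  sel <- peritumor$data != 0L
  if (is.array(scores)) {
    stopifnot(identical(dim(scores), dim(peritumor$data)))
    vals <- scores[sel]
  } else {
    stopifnot(length(scores) == sum(sel))
    vals <- as.numeric(scores)
  }
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1))
    stop("scores must be finite probabilities in [0, 1]")
  data <- array(NA_real_, dim(peritumor$data))
  data[sel] <- vals
  structure(list(data = data, support = peritumor, stage = stage,
                 spacing = peritumor$spacing, axes = peritumor$axes),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  v <- x$data[!is.na(x$data)]
  cat(sprintf("<probability_map> stage %s, %d voxels, scores %.3f..%.3f\n",
              x$stage, length(v), min(v), max(v)))
  invisible(x)
}

map_values <- function(map) map$data[map$support$data != 0L]

#' Distance from the surgical cavity
#'
#' Exact Euclidean distance transform, in world millimetres, from the
#' (edge of the) binary cavity mask: cavity voxels have distance 0, a
#' face-adjacent voxel at 1 mm spacing has distance 1.
#'
#' @param cavity nonempty [mask_volume].
#' @param support optional [mask_volume]; when given, returns the distance
#'   values on the support voxels (array index order) instead of the full
#'   grid.
#' @return a [voxel_grid] of distances, or a numeric vector if `support`
#'   is given.
#' @export
distance_from_cavity <- function(cavity, support = NULL) {
  stopifnot(inherits(cavity, "mask_volume"))
  if (mask_count(cavity) == 0L) stop("empty cavity mask")
  d <- cpp_edt(cavity$data, dim(cavity$data), cavity$spacing)
  if (is.null(support)) return(voxel_grid(d, cavity$spacing, cavity$axes))
  check_same_geometry(cavity, support, "cavity and support")
  d[support$data != 0L]
}

#' Distance-correction configuration
#'
#' Voxels close to the cavity edge are far more likely to harbor
#' infiltration than distant edema, so predicted probabilities beyond a
#' cutoff distance are attenuated: the multiplier is 1 up to `cutoff_mm`
#' and decays exponentially (`exp(-decay * (d - cutoff))`) beyond it —
#' continuous at the cutoff and nonincreasing in distance.
#'
#' @param cutoff_mm distance (mm) beyond which attenuation applies
#'   (default 15).
#' @param decay_rate_per_mm attenuation steepness (default 0.5 per mm).
#' @return a `correction_config` object.
#' @export
correction_config <- function(cutoff_mm = 15, decay_rate_per_mm = 0.5) {
  if (!is.finite(cutoff_mm) || cutoff_mm <= 0) stop("cutoff must be positive")
  if (!is.finite(decay_rate_per_mm) || decay_rate_per_mm <= 0)
    stop("decay rate must be positive")
  structure(list(cutoff_mm = cutoff_mm,
                 decay_rate_per_mm = decay_rate_per_mm),
            class = "correction_config")
}

correction_multiplier <- function(d, config) {
  ifelse(d <= config$cutoff_mm, 1,
         exp(-config$decay_rate_per_mm * (d - config$cutoff_mm)))
}

#' Apply the cavity-distance correction to a probability map
#'
#' @param map a raw-stage [probability_map()].
#' @param distance per-voxel distance in mm on the same support (vector in
#'   array index order, or full array / [voxel_grid]).
#' @param config a [correction_config()].
#' @return a corrected-stage [probability_map()]; applying the correction
#'   twice is an error.
#' @export
distance_correction <- function(map, distance, config = correction_config()) {
  stopifnot(inherits(map, "probability_map"))
  if (map$stage != "raw")
    stop("map is already corrected (stage guard)")
  if (inherits(distance, "voxel_grid")) distance <- distance$data
  sel <- map$support$data != 0L
  d <- if (is.array(distance)) distance[sel] else as.numeric(distance)
  stopifnot(length(d) == sum(sel), all(is.finite(d)), all(d >= 0))
  corrected <- map$data[sel] * correction_multiplier(d, config)
  probability_map(corrected, map$support, stage = "corrected")
}

#' Otsu threshold of a score sample
#'
#' The threshold maximizing between-class variance over a 256-bin
#' histogram of the values; deterministic, with ties resolved to the mean
#' of all maximizing cut points.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return the scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  mn <- min(values)
  mx <- max(values)
  if (mx <= mn) stop("constant input: no threshold exists")
  w <- (mx - mn) / n_bins
  bin <- pmin(as.integer(floor((values - mn) / w)), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  centers <- mn + (seq_len(n_bins) - 0.5) * w
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k
  k <- seq_len(n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  best <- which(sigma_b >= max(sigma_b) - 1e-15)
  mean(mn + best * w)            # cut at the upper edge of bin k
}

#' Predicted recurrence labels from a corrected map
#'
#' Binarizes a corrected-stage probability map at the per-case Otsu
#' threshold of its within-peritumor scores: voxels whose corrected
#' probability exceeds the threshold are labeled recurrence.
#'
#' @param corrected a corrected-stage [probability_map()].
#' @return list with `mask` (predicted [mask_volume]) and `threshold`
#'   (the Otsu cut).
#' @export
predicted_labels <- function(corrected) {
  stopifnot(inherits(corrected, "probability_map"))
  if (corrected$stage != "corrected")
    stop("expected a corrected-stage map")
  v <- map_values(corrected)
  theta <- otsu_threshold(v)
  sel <- corrected$support$data != 0L
  m <- array(0L, dim(corrected$data))
  m[sel] <- as.integer(v > theta)
  list(mask = mask_volume(m, corrected$spacing, corrected$axes),
       threshold = theta)
}
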