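#' Read and write NIfTI-1 volumes
#'
#' Volumes are exchanged as NIfTI-1 (`.nii` / `.nii.gz`).  Spacing is taken
#' from the header `pixdim`, the orientation descriptor from the header
#' xform (never assumed).  A write -> read round trip preserves the array,
#' spacing and orientation exactly (data are stored as float64).
#'
#' @param path file path of a NIfTI-1 image.
#' @param expect_isotropic if `TRUE`, error when voxel spacing is
#'   anisotropic beyond `iso_tol` (relative).
#' @param iso_tol relative tolerance for the isotropy check.
#' @return `read_volume()` returns a [voxel_grid]; `read_mask()` a
#'   [mask_volume] (values binarized at 0.5).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(voxel_grid(array(rnorm(8^3), c(8, 8, 8))), f)
#' g <- read_volume(f)
#' @export
read_volume <- function(path, expect_isotropic = FALSE, iso_tol = 0.01) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected 3D volume")
  spacing <- abs(RNifti::pixdim(img))[seq_len(3L)]
  if (expect_isotropic &&
      (max(spacing) - min(spacing)) / min(spacing) > iso_tol)
    stop(sprintf("expected isotropic spacing, got %s",
                 paste(format(spacing, digits = 4), collapse = "x")))
  ax <- strsplit(RNifti::orientation(img), "")[[1L]]
  voxel_grid(array(as.numeric(img), d), spacing, ax)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  g <- read_volume(path)
  mask_volume(array(as.integer(g$data > 0.5), dim(g$data)), g$spacing, g$axes)
}

#' @rdname read_volume
#' @param grid a [voxel_grid] (or [mask_volume]) to write.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  dt <- if (inherits(grid, "mask_volume")) "uint8" else "double"
  img <- RNifti::asNifti(array(as.numeric(grid$data), dim(grid$data)))
  RNifti::sform(img) <- structure(diag(c(grid$spacing, 1)), code = 2L)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::orientation(img) <- paste(grid$axes, collapse = "")
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Z-score normalization within a mask
#'
#' Centers and scales intensities so that the within-mask mean is 0 and the
#' within-mask standard deviation 1; voxels outside the mask are set to 0.
#' The population (1/n) standard deviation is the default convention.
#'
#' @param grid a [voxel_grid].
#' @param mask a [mask_volume] defining the normalization support (e.g. the
#'   brain mask).
#' @param sd_type `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return a [voxel_grid] with zero mean and unit SD inside the mask.
#' @export
zscore_normalize <- function(grid, mask, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_same_geometry(grid, mask, "image and mask")
  sel <- mask$data != 0L
  if (!any(sel)) stop("mask is empty")
  v <- grid$data[sel]
  if (any(!is.finite(v))) stop("non-finite intensities inside mask")
  m <- mean(v)
  n <- length(v)
  s <- sqrt(sum((v - m)^2) / if (sd_type == "population") n else max(1L, n - 1L))
  if (!is.finite(s) || s < 1e-12)
    stop("constant image within mask: zero variance")
  out <- array(0, dim(grid$data))
  out[sel] <- (v - m) / s
  voxel_grid(out, grid$spacing, grid$axes)
}

#' Resample a volume to isotropic spacing
#'
#' Resamples onto a grid with the requested (isotropic) voxel size, keeping
#' the world extent within one voxel.  Intensity images are interpolated
#' trilinearly; masks nearest-neighbour and re-binarized at 0.5.
#'
#' @param grid a [voxel_grid] or [mask_volume].
#' @param target_mm target voxel size in mm (scalar, applied to all axes).
#' @param method `"auto"` (trilinear for intensities, nearest for masks),
#'   `"trilinear"` or `"nearest"`.
#' @return resampled volume of the same class as the input.
#' @export
resample_isotropic <- function(grid, target_mm = 1,
                               method = c("auto", "trilinear", "nearest")) {
  method <- match.arg(method)
  if (!is.finite(target_mm) || target_mm <= 0) stop("invalid target spacing")
  is_mask <- inherits(grid, "mask_volume")
  if (method == "auto") method <- if (is_mask) "nearest" else "trilinear"

  din <- dim(grid$data)
  if (all(abs(grid$spacing - target_mm) < 1e-9)) return(grid)

  dout <- pmax(2L, as.integer(round((din - 1L) * grid$spacing / target_mm)) + 1L)
  # source voxel coordinate of each output sample, per axis
  src <- lapply(1:3, function(a) {
    u <- (seq_len(dout[a]) - 1) * target_mm / grid$spacing[a]
    pmin(pmax(u, 0), din[a] - 1)
  })
  if (method == "nearest") {
    ix <- lapply(src, function(u) as.integer(round(u)) + 1L)
    out <- grid$data[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
  } else {
    i0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), din[a] - 2))
    fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
    g <- grid$data
    out <- array(0, dout)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wx <- if (cx) fr[[1L]] else 1 - fr[[1L]]
      wy <- if (cy) fr[[2L]] else 1 - fr[[2L]]
      wz <- if (cz) fr[[3L]] else 1 - fr[[3L]]
      blk <- g[i0[[1L]] + cx + 1L, i0[[2L]] + cy + 1L, i0[[3L]] + cz + 1L,
               drop = FALSE]
      w <- outer(outer(wx, wy), wz)
      out <- out + blk * array(w, dout)
    }
  }
  if (is_mask)
    mask_volume(array(as.integer(out > 0.5), dout), rep(target_mm, 3), grid$axes)
  else
    voxel_grid(out, rep(target_mm, 3), grid$axes)
}
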