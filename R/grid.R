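#' Voxel grids and mask volumes
#'
#' A `voxel_grid` is the carrier of all image data in recurmap: a 3D scalar
#' array plus per-axis voxel spacing in millimetres and an orientation
#' descriptor (the anatomical direction in which each array axis increases,
#' e.g. `c("R", "A", "S")` for right / anterior / superior).  A
#' `mask_volume` is a voxel grid whose data are binary (0/1).
#'
#' World coordinates are voxel index (0-based) times spacing along each
#' axis; all millimetre distances in the package are computed in this world
#' space.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm per axis (strictly
#'   positive).
#' @param axes character length-3 orientation descriptor; each element one
#'   of `"R"/"L"`, `"A"/"P"`, `"S"/"I"`.
#' @return `voxel_grid()` returns an object of class `voxel_grid`;
#'   `mask_volume()` an object of class `c("mask_volume", "voxel_grid")`.
#' @examples
#' g <- voxel_grid(array(rnorm(27), c(3, 3, 3)))
#' m <- mask_volume(array(c(1, rep(0, 26)), c(3, 3, 3)))
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), axes = c("R", "A", "S")) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  axes <- validate_axes(axes)
  structure(list(data = data, spacing = spacing, axes = axes),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @export
mask_volume <- function(data, spacing = c(1, 1, 1), axes = c("R", "A", "S")) {
  g <- voxel_grid(data, spacing, axes)
  vals <- unique(as.vector(g$data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be 0/1")
  storage.mode(g$data) <- "integer"
  class(g) <- c("mask_volume", "voxel_grid")
  g
}

validate_axes <- function(axes) {
  axes <- toupper(as.character(axes))
  ok <- c("R", "L", "A", "P", "S", "I")
  if (length(axes) != 3L || !all(axes %in% ok))
    stop("axes must be three of R/L, A/P, S/I")
  pair <- c(R = "x", L = "x", A = "y", P = "y", S = "z", I = "z")
  if (length(unique(pair[axes])) != 3L)
    stop("axes must name three distinct anatomical axes")
  axes
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, axes %s\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              paste(x$axes, collapse = "")))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# shared geometry check used by every operation combining two volumes
check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s differ in array dimensions", what))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop(sprintf("%s differ in voxel spacing", what))
  invisible(TRUE)
}

mask_count <- function(m) sum(m$data != 0L)

as_mask <- function(x, template) {
  mask_volume(array(as.integer(x != 0), dim(template$data)),
              template$spacing, template$axes)
}
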