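#' Image filter bank for voxelwise radiomics
#'
#' Three filters generate derived images from which features are extracted
#' alongside the original volume: a scale-normalized Laplacian of Gaussian
#' (`log_filter`), a one-level separable 3D Haar wavelet decomposition into
#' 8 sub-bands (`wavelet_decompose`), and a rotation-invariant 3D local
#' binary pattern code (`lbp3d`).
#'
#' `log_filter` smooths with an isotropic Gaussian of `sigma_mm` (converted
#' to voxels through the spacing, so the scale is a world-space quantity)
#' and applies the discrete Laplacian in world units, multiplied by
#' `sigma_mm^2` (scale normalization), so blob-like structures of physical
#' size comparable to `sigma_mm` give extremal responses.
#'
#' @param grid a [voxel_grid].
#' @param sigma_mm Gaussian scale in millimetres (> 0).  A scale below half
#'   a voxel triggers a warning and proceeds.
#' @return `log_filter` and `lbp3d` return a [voxel_grid];
#'   `wavelet_decompose` a named list of 8 [voxel_grid]s
#'   (`LLL`, `HLL`, `LHL`, `HHL`, `LLH`, `HLH`, `LHH`, `HHH`; `H` marks the
#'   high-pass axis, x first).
#' @export
log_filter <- function(grid, sigma_mm) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(sigma_mm) || sigma_mm <= 0) stop("sigma must be positive")
  if (sigma_mm < min(grid$spacing) / 2)
    warning("sigma smaller than half a voxel; response will be noise-dominated")
  dm <- dim(grid$data)
  ks <- lapply(1:3, function(a) gauss_kernel_1d(sigma_mm / grid$spacing[a]))
  sm <- cpp_convolve_sep(grid$data, dm, ks[[1L]], ks[[2L]], ks[[3L]])
  lap <- array(0, dm)
  for (a in 1:3) {
    d2 <- c(1, -2, 1) / grid$spacing[a]^2
    k1 <- list(1, 1, 1)
    k1[[a]] <- d2
    lap <- lap + cpp_convolve_sep(sm, dm, k1[[1L]], k1[[2L]], k1[[3L]])
  }
  voxel_grid(sigma_mm^2 * lap, grid$spacing, grid$axes)
}

# orthonormal Haar analysis along one axis; returns list(L, H) at half length
haar_axis <- function(arr, axis) {
  dm <- dim(arr)
  n <- dm[axis]
  if (n %% 2L == 1L) {            # replicate-pad odd axes
    idx <- c(seq_len(n), n)
    arr <- switch(axis,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE])
    n <- n + 1L
  }
  odd <- seq(1L, n, by = 2L)
  even <- odd + 1L
  a <- switch(axis, arr[odd, , , drop = FALSE], arr[, odd, , drop = FALSE],
              arr[, , odd, drop = FALSE])
  b <- switch(axis, arr[even, , , drop = FALSE], arr[, even, , drop = FALSE],
              arr[, , even, drop = FALSE])
  list(L = (a + b) / sqrt(2), H = (a - b) / sqrt(2))
}

upsample2 <- function(arr, target_dim) {
  ix <- lapply(1:3, function(a) rep(seq_len(dim(arr)[a]), each = 2L)[seq_len(target_dim[a])])
  arr[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
}

#' @rdname log_filter
#' @param upsample if `TRUE` (default) each sub-band is brought back to the
#'   source resolution by nearest-neighbour expansion, for voxelwise use;
#'   if `FALSE` the decimated orthonormal coefficients are returned (their
#'   summed energy equals the input energy for even axis lengths).
#' @export
wavelet_decompose <- function(grid, upsample = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  dm <- dim(grid$data)
  if (any(dm < 2L)) stop("each axis length must be at least 2")
  bands <- list(grid$data)
  bnames <- ""
  for (axis in 1:3) {
    nxt <- list()
    nxtnames <- character()
    for (k in seq_along(bands)) {
      lh <- haar_axis(bands[[k]], axis)
      nxt <- c(nxt, list(lh$L, lh$H))
      nxtnames <- c(nxtnames, paste0(bnames[k], "L"), paste0(bnames[k], "H"))
    }
    bands <- nxt
    bnames <- nxtnames
  }
  names(bands) <- bnames
  # names were appended x,y,z; report as e.g. "HLL" = high-pass along x
  order <- c("LLL", "HLL", "LHL", "HHL", "LLH", "HLH", "LHH", "HHH")
  bands <- bands[order]
  lapply(bands, function(b) {
    arr <- if (upsample) upsample2(b, dm) else b
    sp <- if (upsample) grid$spacing else grid$spacing * 2
    voxel_grid(arr, sp, grid$axes)
  })
}

#' @rdname log_filter
#' @details `lbp3d` thresholds the six face neighbours of every voxel
#'   against the centre (ties count as greater-or-equal; edges use
#'   replicate padding) and maps the pattern to its rotation-invariant
#'   count of set bits, giving codes 0..6.
#' @export
lbp3d <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  g <- grid$data
  dm <- dim(g)
  shift <- function(a, axis, by) {
    n <- dm[axis]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  code <- array(0L, dm)
  for (axis in 1:3) for (by in c(-1L, 1L))
    code <- code + (shift(g, axis, by) >= g)
  voxel_grid(array(as.numeric(code), dm), grid$spacing, grid$axes)
}

# expand a feature-config filter list into named filtered images
apply_filter_bank <- function(grid, filters, log_sigma_mm) {
  out <- list()
  for (f in filters) {
    if (f == "original") {
      out[["original"]] <- grid
    } else if (f == "log") {
      for (s in log_sigma_mm)
        out[[sprintf("log-sigma-%g-mm", s)]] <- log_filter(grid, s)
    } else if (f == "wavelet") {
      wb <- wavelet_decompose(grid)
      names(wb) <- paste0("wavelet-", names(wb))
      out <- c(out, wb)
    } else if (f == "lbp") {
      out[["lbp-3D"]] <- lbp3d(grid)
    } else {
      stop(sprintf("unknown filter '%s'", f))
    }
  }
  out
}
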