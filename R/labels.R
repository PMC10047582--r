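#' Derive per-voxel recurrence ground truth
#'
#' Peritumoral voxels overlapping the follow-up enhancing-tumor mask are
#' labeled recurrence (1); non-overlapping peritumoral voxels are labeled
#' nonrecurrence (0).  Voxels of the follow-up mask outside the peritumor
#' are ignored: the analysis support is exactly the peritumoral region.
#'
#' @param peritumor [mask_volume] of the peritumoral region (nonempty).
#' @param followup_enhancing [mask_volume] of the enhancing tumor on the
#'   follow-up scan; may extend beyond the peritumor.
#' @return an object of class `label_volume`: list with `data` (3D integer
#'   array; 1 recurrence, 0 nonrecurrence, 255 outside the peritumor),
#'   `counts` (named voxel counts), `spacing` and `axes`.
#' @examples
#' p <- mask_volume(array(rep(c(1, 0), c(27, 98)), c(5, 5, 5)))
#' f <- mask_volume(array(rep(c(1, 0), c(8, 117)), c(5, 5, 5)))
#' derive_labels(p, f)$counts
#' @export
derive_labels <- function(peritumor, followup_enhancing) {
  stopifnot(inherits(peritumor, "mask_volume"),
            inherits(followup_enhancing, "mask_volume"))
  check_same_geometry(peritumor, followup_enhancing, "masks")
  sel <- peritumor$data != 0L
  if (!any(sel)) stop("empty peritumor mask")
  lab <- array(255L, dim(peritumor$data))
  lab[sel] <- 0L
  lab[sel & followup_enhancing$data != 0L] <- 1L
  counts <- c(recurrence = sum(lab == 1L), nonrecurrence = sum(lab == 0L))
  structure(list(data = lab, counts = counts,
                 spacing = peritumor$spacing, axes = peritumor$axes),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %d recurrence + %d nonrecurrence = %d peritumoral voxels\n",
              x$counts[["recurrence"]], x$counts[["nonrecurrence"]],
              sum(x$counts)))
  invisible(x)
}

#' @rdname derive_labels
#' @param labels a `label_volume`.
#' @param path output NIfTI path; codes are written as an unsigned byte
#'   image with 255 for voxels outside the peritumor.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  img <- RNifti::asNifti(array(as.numeric(labels$data), dim(labels$data)))
  RNifti::sform(img) <- structure(diag(c(labels$spacing, 1)), code = 2L)
  RNifti::pixdim(img) <- labels$spacing
  RNifti::orientation(img) <- paste(labels$axes, collapse = "")
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# per-voxel label vector over the peritumor support, in array index order
label_vector <- function(labels) {
  v <- labels$data[labels$data != 255L]
  as.integer(v)
}
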