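#' Extract mean ROI time series from a 4-D volumetric image
#'
#' For each spherical ROI, column j of the result is the mean, at each
#' timepoint, over all voxels whose center lies within Euclidean distance
#' `radius` (mm) of the ROI center. Voxel centers are mapped to world (MNI)
#' mm coordinates through the image affine, so the image must already be in
#' the same stereotaxic space as the ROI table.
#'
#' @param image A NIfTI file path, an `RNifti` image, or a 4-D array with an
#'   `"affine"` attribute (4 x 4 voxel-index-to-mm matrix, 1-based indices).
#' @param rois A `roi_set`.
#' @return T x N numeric matrix, columns in ROI order, named by abbreviation.
#' @export
extract_roi_timeseries <- function(image, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.character(image)) image <- RNifti::readNifti(image)
  if (inherits(image, "niftiImage")) {
    affine <- .xform_to_r_affine(RNifti::xform(image))
    arr <- as.array(image)
  } else {
    affine <- attr(image, "affine")
    if (is.null(affine)) stop("array image requires an 'affine' attribute")
    arr <- image
  }
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1)
  if (length(dim(arr)) != 4) stop("image must be 3-D or 4-D")
  dm <- dim(arr)
  nvox <- prod(dm[1:3])
  tlen <- dm[4]

  # world coordinates of all voxel centers (1-based indices -> mm)
  idx <- cbind(
    rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]),
    rep(seq_len(dm[3]), each = dm[1] * dm[2])
  )
  world <- cbind(idx, 1) %*% t(affine)

  mat <- matrix(arr, nrow = nvox, ncol = tlen)
  out <- matrix(NA_real_, nrow = tlen, ncol = nrow(rois),
                dimnames = list(NULL, rois$abbrev))
  for (j in seq_len(nrow(rois))) {
    d2 <- (world[, 1] - rois$x[j])^2 + (world[, 2] - rois$y[j])^2 +
      (world[, 3] - rois$z[j])^2
    inside <- d2 <= rois$radius[j]^2
    if (!any(inside))
      stop("ROI '", rois$abbrev[j], "' contains no voxels in this image")
    out[, j] <- colMeans(mat[inside, , drop = FALSE])
  }
  out
}

# RNifti::xform() maps 0-based voxel indices to mm; shift to 1-based.
.xform_to_r_affine <- function(xf) {
  xf <- unclass(xf)
  xf[, 4] <- xf[, 4] - xf[, 1:3] %*% rep(1, 3)
  xf
}
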