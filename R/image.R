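#' 3D image volume with physical spacing
#'
#' Minimal container for a scalar 3D MR volume: a numeric array plus voxel
#' spacing in millimetres and a modality tag. All geometry-aware operations
#' (resampling, physical filters, shape features) read the spacing from here.
#'
#' @param values numeric 3D array (a 2D matrix is promoted to a single-slice
#'   volume).
#' @param spacing numeric length-3 vector, voxel size in mm along (x, y, z).
#' @param modality modality tag, typically `"T1Gd"` or `"T2"`.
#' @return An object of class `gx_image`.
#' @examples
#' img <- gx_image(array(rnorm(8 * 8 * 4), c(8, 8, 4)), spacing = c(1, 1, 5))
#' dim(img)
#' @export
gx_image <- function(values, spacing = c(1, 1, 1), modality = "T1Gd") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers (mm)", call. = FALSE)
  stopifnot_finite(values, "voxel values")
  structure(list(values = values, spacing = spacing, modality = modality),
            class = "gx_image")
}

#' @export
dim.gx_image <- function(x) dim(x$values)

#' @export
as.array.gx_image <- function(x, ...) x$values

#' @export
print.gx_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gx_image %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm>\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

# Replace the voxel array, keeping geometry/modality.
gx_replace <- function(img, values) {
  img$values <- values
  img
}

#' Read / write a volume as NIfTI-1
#'
#' The affine carries the voxel spacing; orientation is identity (volumes in
#' this package are generated co-registered on axis-aligned grids).
#'
#' @param img a [gx_image].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param modality modality tag to attach on read.
#' @return `read_nifti_volume` returns a [gx_image]; `write_nifti_volume`
#'   returns `path` invisibly.
#' @export
write_nifti_volume <- function(img, path) {
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path, modality = "T1Gd") {
  nii <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nii)[1:3]
  gx_image(array(as.numeric(nii), dim(nii)[1:3]), spacing = sp,
           modality = modality)
}
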