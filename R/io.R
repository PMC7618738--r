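#' Save and load shot sets
#'
#' Shot sets are serialized with R's native RDS format (complex k-space has
#' no portable plain-text representation at realistic sizes). The layout
#' mirrors the in-memory structure: `shots`, `masks`, `navigators`,
#' `calibration`, `scheme`, `truth` and the acquisition attributes.
#'
#' @param shotset a `kspace_shotset`.
#' @param path file path.
#' @return `read_shotset()` returns the `kspace_shotset`.
#' @export
write_shotset <- function(shotset, path) {
  stopifnot(inherits(shotset, "kspace_shotset"))
  saveRDS(shotset, path)
  invisible(path)
}

#' @rdname write_shotset
#' @export
read_shotset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "kspace_shotset")) stop("not a shot-set file", call. = FALSE)
  x
}

#' Write a (magnitude) image as NIfTI
#'
#' Thin wrapper over the RNifti package; complex images are written as
#' magnitudes. Requires the suggested RNifti package.
#'
#' @param image matrix or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel size(s) in mm.
#' @export
write_image_nifti <- function(image, path, pixdim = 1) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package", call. = FALSE)
  }
  if (is.complex(image)) image <- Mod(image)
  arr <- if (length(dim(image)) == 2L) array(image, c(dim(image), 1L)) else image
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep_len(pixdim, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI requires the RNifti package", call. = FALSE)
  }
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1]
  arr
}
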