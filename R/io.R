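#' Read a DWI dataset (NIfTI + FSL gradient table)
#'
#' @param nifti_path 4D NIfTI volume (x, y, z, N).
#' @param bval_path,bvec_path FSL-dialect gradient table files.
#' @param mask_path optional 3D mask NIfTI.
#' @return A list of class \code{"dwi_dataset"}: \code{data} (4D array),
#'   \code{affine} (4x4), \code{scheme}, \code{mask} (logical vector or
#'   NULL).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask_path = NULL) {
  if (!file.exists(nifti_path)) stop("DWI volume not found: ", nifti_path)
  img <- RNifti::readNifti(nifti_path)
  arr <- nifti_array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D DWI volume, got ", length(dim(arr)), "D: ",
         nifti_path)
  scheme <- read_gradients(bval_path, bvec_path)
  if (dim(arr)[4] != length(scheme$bvals))
    stop("count mismatch: ", dim(arr)[4], " volumes vs ",
         length(scheme$bvals), " gradient-table entries")
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- nifti_array(RNifti::readNifti(mask_path))
    if (!all(dim(m) == dim(arr)[1:3]))
      stop("mask grid does not match DWI grid: ", mask_path)
    mask <- as.logical(m > 0)
  }
  structure(list(data = arr, affine = unclass(RNifti::xform(img)),
                 scheme = scheme, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat("DWI dataset:", paste(dim(x$data), collapse = " x "), "\n")
  print(x$scheme)
  invisible(x)
}

# internal: write an array as NIfTI. Affines here are always axis-aligned
# RAS voxel scalings, carried by pixdim (which survives serialization).
write_nifti_vol <- function(arr, affine, path, datatype = "float") {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(img))
  if (!is.null(affine))
    RNifti::pixdim(img) <- c(abs(diag(affine)[1:3]),
                             rep(1, max(0, nd - 3)))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# internal: plain array from a niftiImage (drop header attributes)
nifti_array <- function(img) {
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' Write a DWI dataset (NIfTI + FSL gradient table)
#'
#' @param data 4D array (x, y, z, N).
#' @param scheme a \code{\link{gradient_scheme}}.
#' @param affine 4x4 affine (RAS, mm); NULL for identity.
#' @param nifti_path,bval_path,bvec_path output paths (NIfTI is written
#'   compressed; use a .nii.gz name).
#' @return Invisibly, the three paths.
#' @export
write_dwi <- function(data, scheme, affine, nifti_path, bval_path,
                      bvec_path) {
  if (length(dim(data)) != 4L) stop("data must be 4D (x, y, z, N)")
  if (dim(data)[4] != length(scheme$bvals))
    stop("count mismatch: ", dim(data)[4], " volumes vs ",
         length(scheme$bvals), " gradient entries")
  write_nifti_vol(data, affine, nifti_path)
  write_gradients(scheme, bval_path, bvec_path)
  invisible(c(nifti_path, bval_path, bvec_path))
}

#' Read / write an integer label volume
#'
#' @param path NIfTI file.
#' @return \code{read_labels}: an integer 3D array with the file's affine in
#'   attribute \code{"affine"}.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label volume not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- nifti_array(img)
  out <- array(as.integer(round(arr)), dim = dim(arr))
  attr(out, "affine") <- unclass(RNifti::xform(img))
  out
}

#' @rdname read_labels
#' @param labels integer 3D array.
#' @param affine 4x4 affine.
#' @export
write_labels <- function(labels, affine, path) {
  write_nifti_vol(array(as.integer(labels), dim = dim(labels)), affine,
                  path, datatype = "int32")
}

#' Write per-metric NIfTI maps
#'
#' One compressed NIfTI per metric; invalid voxels are encoded as NaN (the
#' on-disk sentinel).
#'
#' @param maps named list of 3D arrays on a shared grid (e.g. from
#'   \code{\link{metric_maps}}).
#' @param affine 4x4 affine.
#' @param prefix output path prefix; files are written as
#'   \code{<prefix>_<metric>.nii.gz}.
#' @return Invisibly, a named vector of file paths.
#' @export
write_metric_maps <- function(maps, affine, prefix) {
  dims <- lapply(maps, dim)
  if (length(unique(lapply(dims, paste, collapse = "x"))) != 1L)
    stop("metric volumes do not share a grid")
  out <- vapply(names(maps), function(m) {
    path <- paste0(prefix, "_", m, ".nii.gz")
    write_nifti_vol(maps[[m]], affine, path)
    path
  }, character(1))
  invisible(out)
}

#' Read metric maps written by \code{\link{write_metric_maps}}
#'
#' @param prefix path prefix used when writing.
#' @param metrics metric names to read.
#' @return A named list of 3D arrays (NaN marks invalid voxels).
#' @export
read_metric_maps <- function(prefix,
                             metrics = c("fa", "cl", "cp", "cs", "md")) {
  out <- lapply(metrics, function(m) {
    path <- paste0(prefix, "_", m, ".nii.gz")
    if (!file.exists(path)) stop("metric map not found: ", path)
    nifti_array(RNifti::readNifti(path))
  })
  names(out) <- metrics
  out
}
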