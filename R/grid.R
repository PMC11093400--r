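# Common analysis grid and NIfTI volume I/O.

#' Define a volumetric analysis grid
#'
#' All stages of the pipeline operate on a single common grid, the synthetic
#' stand-in for a standard-space template. The affine maps 0-based voxel
#' indices to world coordinates in mm (RAS+, NIfTI convention).
#'
#' @param shape Integer triple: voxels per axis.
#' @param voxel_size_mm Positive triple: voxel edge lengths in mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   RAS+ affine built from `voxel_size_mm` with the origin at voxel (0,0,0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("affine must be invertible")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s voxels, %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$voxel_size_mm), collapse = " x ")))
  invisible(x)
}

#' @rdname volume_grid
#' @param x Object to test.
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

# Map 0-based voxel indices (n x 3) to world mm coordinates (n x 3).
vox_to_world <- function(grid, ijk0) {
  ijk0 <- matrix(as.numeric(ijk0), ncol = 3)
  h <- cbind(ijk0, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol Numeric, integer or logical 3-D array.
#' @param grid A [volume_grid()] supplying voxel sizes and the affine.
#' @param file Output path (`.nii`; uncompressed so repeated runs are
#'   byte-identical).
#' @param datatype NIfTI storage type, e.g. "double" or "int32".
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, grid, file, datatype = "double") {
  stopifnot(is_volume_grid(grid), identical(dim(vol), dim(array(0, grid$shape))))
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim(vol))
    datatype <- "int32"
  }
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, grid$voxel_size_mm)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, file, datatype = datatype)
  invisible(file)
}

#' Read a NIfTI-1 volume together with its grid
#'
#' @param file Path to a 3-D NIfTI file.
#' @return List with elements `data` (plain array) and `grid` ([volume_grid()]).
#' @export
read_volume <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- RNifti::xform(img)
  pd <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, grid = volume_grid(dim(arr), pd, matrix(aff, 4, 4)))
}
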