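#' Write an SUV volume (or mask) as NIfTI-1
#'
#' @param x an \linkS4class{SUVVolume}, \linkS4class{DelineationMask}, or
#'   3-D array (logical masks are written as integer volumes).
#' @param path output file path (\code{.nii} or \code{.nii.gz}).
#' @param voxelSize voxel edge lengths in mm for plain arrays.
#' @return The path, invisibly.
#' @export
writeNiftiVolume <- function(x, path, voxelSize = c(1, 1, 1)) {
  if (is(x, "SUVVolume")) {
    arr <- suvValues(x)
    vs <- voxelSize(x)
  } else if (is(x, "DelineationMask")) {
    arr <- array(as.integer(x@mask), dim = dim(x@mask))
    vs <- voxelSize(x)
  } else {
    arr <- if (is.logical(x)) array(as.integer(x), dim = dim(x)) else x
    vs <- if (length(voxelSize) == 1L) rep(voxelSize, 3L) else voxelSize
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as an SUVVolume
#'
#' @param path a NIfTI file.
#' @param timepoint acquisition tag to attach, \code{"T10"} or
#'   \code{"T60"}.
#' @return An \linkS4class{SUVVolume}.
#' @export
readSUVVolume <- function(path, timepoint = "T10") {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  SUVVolume(array(as.numeric(img), dim = dim(img)[1:3]),
            voxelSize = vs, timepoint = timepoint)
}

#' Write all phantom volumes to a directory
#'
#' Writes the two SUV volumes, the integer tissue label map, and the
#' FLAIR and CE masks as NIfTI-1 files.
#'
#' @param phantom the list returned by \code{\link{generatePhantom}}.
#' @param dir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
writePhantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vs <- voxelSize(phantom$vol10)
  paths <- c(
    suv10 = file.path(dir, "suv_t10.nii.gz"),
    suv60 = file.path(dir, "suv_t60.nii.gz"),
    labels = file.path(dir, "labels.nii.gz"),
    flair = file.path(dir, "flair_mask.nii.gz"),
    ce = file.path(dir, "ce_mask.nii.gz"))
  writeNiftiVolume(phantom$vol10, paths["suv10"])
  writeNiftiVolume(phantom$vol60, paths["suv60"])
  writeNiftiVolume(phantom$labels, paths["labels"], voxelSize = vs)
  writeNiftiVolume(phantom$flair, paths["flair"], voxelSize = vs)
  writeNiftiVolume(phantom$ce, paths["ce"], voxelSize = vs)
  invisible(paths)
}
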