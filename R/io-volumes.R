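#' Read a NIfTI volume with its grid
#'
#' The sform/qform affine is preserved exactly; no resampling or
#' reorientation is ever performed.
#'
#' @param path NIfTI-1/2 file.
#' @param binarize threshold the data at > 0.5 into an integer mask.
#' @return list with `data` (array) and `grid` ([VoxelGrid-class]).
#' @export
readVolume <- function(path, binarize = FALSE) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  aff <- if (hdr$sform_code > 0)
    rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  else matrix(structure(RNifti::xform(img), dim = c(4L, 4L)), 4, 4)
  grid <- voxelGrid(dim(img)[1:3], affine = aff)
  data <- array(as.vector(img), dim = dim(img))
  if (binarize) data <- array(as.integer(data > 0.5), dim = dim(data))
  list(data = data, grid = grid)
}

#' Write an array as NIfTI on a given grid
#'
#' @param data 3-D or 4-D array.
#' @param grid a [VoxelGrid-class]; its affine becomes the sform/qform.
#' @param path output path (.nii or .nii.gz).
#' @export
writeVolume <- function(data, grid, path) {
  img <- RNifti::asNifti(data)
  aff <- gridAffine(grid)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two grids agree (no silent resampling)
#'
#' @param a,b [VoxelGrid-class] objects.
#' @param tol absolute tolerance on affine entries.
#' @export
checkSameGrid <- function(a, b, tol = 1e-4) {
  if (!all(gridDim(a) == gridDim(b)) ||
      max(abs(gridAffine(a) - gridAffine(b))) > tol)
    stop("grid mismatch between paired inputs: ",
         "dims ", paste(gridDim(a), collapse = "x"), " vs ",
         paste(gridDim(b), collapse = "x"),
         "; max affine deviation ",
         format(max(abs(gridAffine(a) - gridAffine(b)))))
  invisible(TRUE)
}

#' FSL-style gradient table I/O
#'
#' `.bval` holds one space-separated row of b-values; `.bvec` three rows
#' (x, y, z components), one column per volume.
#'
#' @param bvalPath,bvecPath text file paths.
#' @return A [GradientTable-class].
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecs <- matrix(scan(bvecPath, quiet = TRUE), nrow = 3L, byrow = TRUE)
  gradientTable(bvals, t(bvecs))
}

#' @rdname readBvalBvec
#' @param gtab a [GradientTable-class].
#' @export
writeBvalBvec <- function(gtab, bvalPath, bvecPath) {
  writeLines(paste(format(bValues(gtab), trim = TRUE), collapse = " "),
             bvalPath)
  v <- t(bVectors(gtab))
  writeLines(apply(v, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvecPath)
  invisible(bvalPath)
}
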