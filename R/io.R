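#' Write an array as NIfTI-1 with a RAS affine
#'
#' @param arr 3-D or 4-D numeric array.
#' @param affine 4 x 4 voxel-to-world matrix (0-based indices, RAS).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_nifti <- function(arr, affine, path) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(arr, pixdim = vox)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @return List with `data` (plain array) and `affine` (4 x 4 matrix).
#' @export
read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, affine = aff)
}

#' Write FSL-style gradient tables
#'
#' `.bval`: one row of b-values. `.bvec`: three rows with the x, y and z
#' components of each direction.
#'
#' @param scheme An [acquisition_scheme()].
#' @param prefix Path prefix; writes `<prefix>.bval` and `<prefix>.bvec`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_bvalbvec <- function(scheme, prefix) {
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval)
  writeLines(vapply(1:3, function(k)
    paste(sprintf("%.16g", scheme$bvecs[, k]), collapse = " "),
    character(1)), bvec)
  invisible(c(bval = bval, bvec = bvec))
}

#' Read FSL-style gradient tables
#'
#' Nonzero directions are renormalised to unit length to absorb text
#' round-off.
#'
#' @param bval,bvec File paths.
#' @return An [acquisition_scheme()].
#' @export
read_bvalbvec <- function(bval, bvec) {
  bvals <- scan(bval, quiet = TRUE)
  comp <- do.call(rbind, lapply(readLines(bvec), function(l)
    scan(text = l, quiet = TRUE)))
  if (nrow(comp) != 3L || ncol(comp) != length(bvals))
    stop("bvec must have 3 rows matching the number of b-values")
  bvecs <- t(comp)
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  acquisition_scheme(bvals, bvecs)
}

#' Write a simulated DWI series with its gradient tables
#'
#' @param dwi An `alps_dwi`.
#' @param prefix Path prefix; writes `<prefix>.nii.gz`, `.bval`, `.bvec`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  write_nifti(dwi$data, dwi$affine, nii)
  gt <- write_bvalbvec(dwi$scheme, prefix)
  invisible(c(nii = nii, gt))
}

#' Read a DWI series with its gradient tables
#'
#' @param nii NIfTI path.
#' @param bval,bvec Gradient table paths.
#' @return An `alps_dwi`.
#' @export
read_dwi <- function(nii, bval, bvec) {
  vol <- read_nifti(nii)
  scheme <- read_bvalbvec(bval, bvec)
  if (dim(vol$data)[4] != length(scheme$bvals))
    stop("DWI volume count does not match the gradient table")
  structure(list(data = vol$data, affine = vol$affine, scheme = scheme),
            class = "alps_dwi")
}
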