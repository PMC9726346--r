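#' Design matrix of the log-linear tensor model
#'
#' Row i of the design maps the unknown vector
#' `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, log S0)` to the log-signal of volume i:
#' `[-b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz, 1]`.
#'
#' @param scheme An [acquisition_scheme()].
#' @return A numeric matrix with one row per volume and seven columns.
#' @export
design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "alps_scheme"))
  g <- scheme$bvecs
  b <- scheme$bvals
  cbind(-b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3], 1)
}

fa_from_evals <- function(ev) {
  # ev: n x 3 matrix. FA = sqrt(3/2) * ||lambda - mean|| / ||lambda||.
  m <- rowMeans(ev)
  num <- (ev[, 1] - m)^2 + (ev[, 2] - m)^2 + (ev[, 3] - m)^2
  den <- ev[, 1]^2 + ev[, 2]^2 + ev[, 3]^2
  fa <- sqrt(pmax(0, 1.5 * num / pmax(den, .Machine$double.xmin)))
  fa[den == 0] <- 0
  pmin(fa, 1)
}

#' Fit per-voxel diffusion tensors by log-linear least squares
#'
#' Ordinary least squares on the log-signal, followed by one weighted
#' refinement pass with weights equal to the squared predicted signal (the
#' first-order variance correction for log-transformed Rician/Gaussian
#' noise). Each voxel's tensor is eigendecomposed with eigenvalues in
#' descending order; negative eigenvalues are clamped to zero and the voxel
#' flagged. Signals are floored at `1e-8 * S0_ref` before the log, and
#' floored voxels are flagged as well; flagged voxels are excluded from ROI
#' statistics downstream.
#'
#' @param dwi An `alps_dwi` (from [simulate_dwi()] or [read_dwi()]).
#' @param mask Optional logical array selecting voxels to fit. Default: all
#'   voxels whose mean b = 0 signal exceeds 25 % of the image maximum (a
#'   simple foreground threshold; pass an explicit brain mask for anything
#'   quantitative).
#' @return An object of class `alps_tensor_field`: list with `tensor`
#'   (nx x ny x nz x 6; Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `evals`
#'   (descending, clamped at 0), `evec1` (principal eigenvector), `fa`, `md`,
#'   `s0` (estimated), `flags` (logical; clamped or floored), `mask`,
#'   `affine`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "alps_dwi"))
  scheme <- dwi$scheme
  X <- design_matrix(scheme)
  if (nrow(X) < 7L || qr(X)$rank < 7L)
    stop("acquisition scheme does not span the tensor model ",
         "(design matrix rank below 7)")
  dim4 <- dim(dwi$data)
  dim3 <- dim4[1:3]
  nvol <- dim4[4]
  vol <- matrix(dwi$data, ncol = nvol)
  b0 <- scheme$bvals == 0
  if (is.null(mask)) {
    b0mean <- rowMeans(vol[, b0, drop = FALSE])
    mask <- array(b0mean > 0.25 * max(b0mean), dim = dim3)
  }
  stopifnot(identical(dim(mask), as.integer(dim3)) ||
            identical(dim(mask), dim3))
  idx <- which(mask)
  if (!length(idx)) stop("empty fit mask")
  S <- vol[idx, , drop = FALSE]
  s0_ref <- mean(S[, b0])
  floor_val <- 1e-8 * s0_ref
  floored <- rowSums(S < floor_val) > 0
  logS <- log(pmax(S, floor_val))
  # OLS, all voxels at once
  XtX <- crossprod(X)
  beta <- t(solve(XtX, crossprod(X, t(logS))))
  # one WLS refinement pass per voxel, weights = predicted squared signal
  for (v in seq_len(nrow(beta))) {
    w <- as.vector(exp(X %*% beta[v, ]))^2
    Xw <- X * w
    beta[v, ] <- solve(crossprod(Xw, X), crossprod(Xw, logS[v, ]))
  }
  nvox <- prod(dim3)
  tensor <- matrix(0, nvox, 6)
  tensor[idx, ] <- beta[, 1:6]
  s0map <- array(0, dim = dim3)
  s0map[idx] <- exp(beta[, 7])
  evals <- matrix(0, nvox, 3)
  evec1 <- matrix(0, nvox, 3)
  clamped <- logical(nrow(beta))
  for (v in seq_along(idx)) {
    d <- beta[v, 1:6]
    Dm <- matrix(c(d[1], d[4], d[5],
                   d[4], d[2], d[6],
                   d[5], d[6], d[3]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)
    if (any(e$values < 0)) {
      clamped[v] <- TRUE
      e$values <- pmax(e$values, 0)
    }
    evals[idx[v], ] <- e$values
    evec1[idx[v], ] <- e$vectors[, 1]
  }
  flags <- array(FALSE, dim = dim3)
  flags[idx] <- clamped | floored
  structure(list(
    tensor = array(tensor, dim = c(dim3, 6)),
    evals = array(evals, dim = c(dim3, 3)),
    evec1 = array(evec1, dim = c(dim3, 3)),
    fa = array(replace(numeric(nvox), idx,
                       fa_from_evals(evals[idx, , drop = FALSE])),
               dim = dim3),
    md = array(rowMeans(evals), dim = dim3),
    s0 = s0map,
    flags = flags,
    mask = array(as.logical(mask), dim = dim3),
    affine = dwi$affine
  ), class = "alps_tensor_field")
}

#' Diffusivity maps along the world x, y and z axes
#'
#' Returns the diagonal tensor entries in the world frame. The voxel-to-world
#' affine must be axis-aligned (its rotation part diagonal); oblique
#' acquisitions are not supported and raise an error.
#'
#' @param field An [fit_tensor()] result (or an `alps_phantom`).
#' @return List with arrays `dxx`, `dyy`, `dzz` (mm^2/s).
#' @export
axis_diffusivities <- function(field) {
  aff <- field$affine[1:3, 1:3]
  if (max(abs(aff - diag(diag(aff)))) > 1e-6 * max(abs(aff)))
    stop("unsupported orientation: the voxel-to-world affine is oblique; ",
         "axis diffusivities require an axis-aligned (RAS) grid")
  list(dxx = field$tensor[, , , 1],
       dyy = field$tensor[, , , 2],
       dzz = field$tensor[, , , 3])
}

#' Color-coded FA map
#'
#' Standard directional color coding: RGB = FA * |principal eigenvector|,
#' with red = x (right-left, the perivascular direction at the measurement
#' slice), green = y (association fibers), blue = z (projection fibers),
#' clipped to [0, 1].
#'
#' @param field An [fit_tensor()] result.
#' @return An nx x ny x nz x 3 array with values in [0, 1].
#' @export
color_fa <- function(field) {
  stopifnot(inherits(field, "alps_tensor_field"))
  dim3 <- dim(field$fa)
  rgb <- abs(matrix(field$evec1, ncol = 3)) * as.vector(field$fa)
  array(pmin(pmax(rgb, 0), 1), dim = c(dim3, 3))
}
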