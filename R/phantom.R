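#' @importFrom stats rnorm runif quantile sd
NULL

# Fixed tissue diffusivities (mm^2/s). White-matter transverse and parallel
# eigenvalues are literature-typical values; CSF is free water at body
# temperature. Per-subject ALPS variation enters only through the x-axis
# eigenvalue of the projection/association regions.
.alps_defaults <- list(
  lambda_perp = 0.3e-3,
  lambda_par  = 1.4e-3,
  csf_adc     = 3.0e-3,
  s0_tissue   = 100
)

#' Tissue tensor specification
#'
#' A diagonal (axis-aligned) diffusion tensor for one phantom region. At the
#' lateral-ventricle-body slice the modelled geometry is axis-aligned:
#' projection fibers run along z, association fibers along y, subcortical
#' fibers along x, and the perivascular direction is x.
#'
#' @param region One of `"projection"`, `"association"`, `"subcortical"`,
#'   `"csf"`, `"background"`.
#' @param eigenvalues Named numeric vector `c(x = , y = , z = )` of
#'   diffusivities along the world axes, mm^2/s, all positive.
#' @param principal_axis The axis (`"x"`, `"y"` or `"z"`) carrying the largest
#'   eigenvalue. Projection regions must have `"z"`, association `"y"`.
#' @return An object of class `alps_tissue_spec`.
#' @export
tissue_tensor_spec <- function(region, eigenvalues, principal_axis) {
  region <- match.arg(region,
    c("projection", "association", "subcortical", "csf", "background"))
  principal_axis <- match.arg(principal_axis, c("x", "y", "z"))
  ev <- eigenvalues[c("x", "y", "z")]
  if (any(is.na(ev)) || any(ev <= 0))
    stop("eigenvalues must be a named positive vector with entries x, y, z")
  if (region == "projection" && principal_axis != "z")
    stop("projection fibers must have principal axis z")
  if (region == "association" && principal_axis != "y")
    stop("association fibers must have principal axis y")
  if (ev[principal_axis] < max(ev) - 1e-15)
    stop("principal_axis must carry the largest eigenvalue")
  structure(list(region = region, eigenvalues = ev,
                 principal_axis = principal_axis),
            class = "alps_tissue_spec")
}

#' Invert the ALPS formula into region tensors
#'
#' Given a target ALPS index, returns the projection- and association-region
#' tensors that realise it. The ALPS index is
#' `mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)`; fixing the
#' fiber-transverse eigenvalue at `baseline` and the fiber-parallel eigenvalue
#' at `parallel`, the target is realised by setting the x-axis eigenvalue of
#' both regions to `target_alps * baseline`.
#'
#' @param target_alps Target ALPS index (> 0).
#' @param baseline Fiber-transverse diffusivity lambda-perp, mm^2/s.
#' @param parallel Fiber-parallel diffusivity lambda-par, mm^2/s.
#' @return A list with elements `projection` and `association`, each an
#'   [tissue_tensor_spec()].
#' @examples
#' tt <- alps_to_tensors(1.5)
#' tt$projection$eigenvalues[["x"]]  # 0.45e-3
#' @export
alps_to_tensors <- function(target_alps,
                            baseline = .alps_defaults$lambda_perp,
                            parallel = .alps_defaults$lambda_par) {
  if (!is.finite(target_alps) || target_alps <= 0)
    stop("'target_alps' must be a positive number")
  if (baseline <= 0 || parallel <= 0)
    stop("diffusivities must be positive")
  if (target_alps * baseline >= parallel)
    stop(sprintf(paste0(
      "invalid ALPS target %.4g: target * baseline = %.4g mm^2/s must stay ",
      "below the fiber-parallel diffusivity %.4g mm^2/s ",
      "(bound: target < %.4g)"),
      target_alps, target_alps * baseline, parallel, parallel / baseline))
  lam_x <- target_alps * baseline
  list(
    projection = tissue_tensor_spec("projection",
      c(x = lam_x, y = baseline, z = parallel), "z"),
    association = tissue_tensor_spec("association",
      c(x = lam_x, y = parallel, z = baseline), "y")
  )
}

#' Analytic ALPS index of a projection/association tensor pair
#'
#' @param projection,association `alps_tissue_spec` objects (or a list with
#'   both, passed as the first argument).
#' @return The noise-free ALPS index implied by the region eigenvalues.
#' @export
analytic_alps <- function(projection, association = NULL) {
  if (is.null(association)) {
    association <- projection$association
    projection <- projection$projection
  }
  num <- mean(c(projection$eigenvalues[["x"]], association$eigenvalues[["x"]]))
  den <- mean(c(projection$eigenvalues[["y"]], association$eigenvalues[["z"]]))
  num / den
}

# Canonical region blocks as 0-based index ranges on a 64 x 64 x 16 grid;
# other grids scale these proportionally. Left hemisphere occupies low x
# (world left under the RAS affine); right-hemisphere blocks are mirror
# images about the mid-sagittal plane.
.canonical_regions <- list(
  projection  = list(x = c(12, 16), y = c(30, 34)),
  association = list(x = c(12, 16), y = c(42, 46)),
  subcortical = list(x = c(4, 8),   y = c(36, 40))
)
.canonical_csf <- list(x = c(28, 35), y = c(30, 44))
.canonical_z <- c(6, 10)
.canonical_dim <- c(64, 64, 16)

#' Region label codes used in phantom label maps
#' @return Named integer vector mapping region names to label values.
#' @export
region_labels <- function() {
  c(csf = 1L,
    projection_left = 2L, association_left = 3L, subcortical_left = 4L,
    projection_right = 5L, association_right = 6L, subcortical_right = 7L)
}

#' Default phantom layout
#'
#' Builds the voxel grid, RAS affine and region label map of the digital
#' phantom: one projection-, association- and subcortical-fiber block per
#' hemisphere, mirror-symmetric about the mid-sagittal plane, plus a midline
#' CSF block standing in for the lateral-ventricle bodies. The default grid is
#' 64 x 64 x 16 voxels of 1.875 x 1.875 x 2.5 mm (the in-plane resolution of a
#' 128 matrix over a 240 mm field of view, and 2.5 mm slices, over a cropped
#' extent). Other grid sizes scale the region blocks proportionally.
#'
#' @param dim Integer grid size `c(nx, ny, nz)`.
#' @param voxel Voxel edge lengths in mm `c(dx, dy, dz)`.
#' @return An object of class `alps_layout`: list with `dim`, `voxel`,
#'   `affine` (voxel-to-world, RAS, 0-based indices), `labels` (integer
#'   array), and `region_labels`.
#' @export
default_layout <- function(dim = c(64L, 64L, 16L),
                           voxel = c(1.875, 1.875, 2.5)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L),
            length(voxel) == 3L, all(voxel > 0))
  sc <- dim / .canonical_dim
  rng <- function(r, s) {
    lo <- floor(r[1] * s)
    hi <- max(lo, floor(r[2] * s))
    c(lo, hi)
  }
  nx <- dim[1]
  labels <- array(0L, dim = dim)
  lab <- region_labels()
  zr <- rng(.canonical_z, sc[3])
  zi <- (zr[1]:zr[2]) + 1L
  put <- function(labels, xr, yr, code) {
    xi <- (xr[1]:xr[2]) + 1L
    yi <- (yr[1]:yr[2]) + 1L
    if (any(labels[xi, yi, zi] != 0L))
      stop("phantom layout regions overlap; grid too small")
    labels[xi, yi, zi] <- code
    labels
  }
  mirror <- function(xr) c(nx - 1 - xr[2], nx - 1 - xr[1])
  for (reg in names(.canonical_regions)) {
    xr <- rng(.canonical_regions[[reg]]$x, sc[1])
    yr <- rng(.canonical_regions[[reg]]$y, sc[2])
    labels <- put(labels, xr, yr, lab[[paste0(reg, "_left")]])
    labels <- put(labels, mirror(xr), yr, lab[[paste0(reg, "_right")]])
  }
  labels <- put(labels, rng(.canonical_csf$x, sc[1]),
                rng(.canonical_csf$y, sc[2]), lab[["csf"]])
  affine <- diag(c(voxel, 1))
  affine[1:3, 4] <- -(dim - 1) / 2 * voxel
  structure(list(dim = dim, voxel = voxel, affine = affine,
                 labels = labels, region_labels = lab),
            class = "alps_layout")
}

# World coordinates of all voxel centers (0-based indices through the affine).
# Returns an n-voxel x 3 matrix in grid storage order.
voxel_centers <- function(dim, affine) {
  ijk <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                               k = 0:(dim[3] - 1)))
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

#' Realise a subject's tensor field on a phantom layout
#'
#' Paints each labeled region with its diagonal tensor: projection and
#' association blocks from the per-hemisphere specs (which encode the
#' subject's true ALPS), an x-oriented subcortical block, isotropic CSF, and
#' zero-signal background.
#'
#' @param layout An [default_layout()] object.
#' @param left,right Per-hemisphere lists with `projection` and `association`
#'   [tissue_tensor_spec()]s, e.g. from [alps_to_tensors()]. A subject row
#'   from [sample_cohort()] can be passed via `subject`.
#' @param subject Optional `alps_subject_truth` (overrides `left`/`right`).
#' @param s0 Baseline (b = 0) signal in labeled tissue, arbitrary units.
#' @param csf_adc Isotropic CSF diffusivity, mm^2/s.
#' @param subcortical Optional `alps_tissue_spec` for the subcortical blocks;
#'   defaults to an x-oriented fiber with the standard eigenvalues.
#' @return An object of class `alps_phantom`: list with `tensor`
#'   (nx x ny x nz x 6 array, components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#'   `s0`, `labels`, `affine`, `layout`.
#' @export
build_phantom <- function(layout, left = NULL, right = NULL, subject = NULL,
                          s0 = .alps_defaults$s0_tissue,
                          csf_adc = .alps_defaults$csf_adc,
                          subcortical = NULL) {
  stopifnot(inherits(layout, "alps_layout"))
  if (!is.null(subject)) {
    left <- subject$left
    right <- subject$right
  }
  if (is.null(left) || is.null(right))
    stop("both hemisphere tensor specs are required (left, right)")
  if (is.null(subcortical))
    subcortical <- tissue_tensor_spec("subcortical",
      c(x = .alps_defaults$lambda_par, y = .alps_defaults$lambda_perp,
        z = .alps_defaults$lambda_perp), "x")
  lab <- layout$region_labels
  specs <- list(left, right)
  names(specs) <- c("left", "right")
  tensor <- array(0, dim = c(layout$dim, 6))
  s0map <- array(0, dim = layout$dim)
  tmat <- matrix(tensor, ncol = 6)
  fill <- function(code, ev) {
    idx <- which(layout$labels == code)
    if (!length(idx))
      stop("layout has no voxels labeled ", names(lab)[lab == code],
           " (code ", code, ")")
    tmat[idx, 1:3] <<- rep(ev, each = length(idx))
    s0map[idx] <<- s0
    invisible(NULL)
  }
  for (h in c("left", "right")) {
    fill(lab[[paste0("projection_", h)]],
         specs[[h]]$projection$eigenvalues[c("x", "y", "z")])
    fill(lab[[paste0("association_", h)]],
         specs[[h]]$association$eigenvalues[c("x", "y", "z")])
    fill(lab[[paste0("subcortical_", h)]],
         subcortical$eigenvalues[c("x", "y", "z")])
  }
  fill(lab[["csf"]], rep(csf_adc, 3))
  structure(list(tensor = array(tmat, dim = c(layout$dim, 6)), s0 = s0map,
                 labels = layout$labels, affine = layout$affine,
                 layout = layout),
            class = "alps_phantom")
}

#' Simulate a diffusion-weighted acquisition of a phantom
#'
#' Evaluates the single-tensor signal model `S = S0 * exp(-b g' D g)` for
#' every volume of the scheme and corrupts it with Rician noise: the magnitude
#' of `(S + e1, e2)` with `e1, e2 ~ N(0, sigma)` and `sigma = S0_ref / snr`,
#' where `S0_ref` is the mean baseline signal over nonzero-S0 voxels.
#'
#' @param phantom An [build_phantom()] object.
#' @param scheme An [acquisition_scheme()].
#' @param snr Signal-to-noise ratio of the reference b = 0 signal; `Inf` for
#'   a noiseless acquisition. Must be positive.
#' @param seed Optional integer seed; when given the simulation is a pure
#'   function of (phantom, scheme, snr, seed).
#' @return An object of class `alps_dwi`: list with `data`
#'   (nx x ny x nz x nvol array), `affine`, `scheme`.
#' @export
simulate_dwi <- function(phantom, scheme, snr = 40, seed = NULL) {
  stopifnot(inherits(phantom, "alps_phantom"), inherits(scheme, "alps_scheme"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("'snr' must be a positive number (or Inf for noiseless)")
  if (!is.null(seed)) set.seed(seed)
  g <- scheme$bvecs
  b <- scheme$bvals
  B <- cbind(b * g[, 1]^2, b * g[, 2]^2, b * g[, 3]^2,
             2 * b * g[, 1] * g[, 2], 2 * b * g[, 1] * g[, 3],
             2 * b * g[, 2] * g[, 3])
  dim3 <- dim(phantom$s0)
  Dmat <- matrix(phantom$tensor, ncol = 6)
  s0v <- as.vector(phantom$s0)
  S <- matrix(0, nrow = length(s0v), ncol = length(b))
  tissue <- which(s0v > 0)
  if (length(tissue))
    S[tissue, ] <- s0v[tissue] * exp(-(Dmat[tissue, , drop = FALSE] %*% t(B)))
  if (is.finite(snr)) {
    s0_ref <- mean(s0v[s0v > 0])
    sigma <- s0_ref / snr
    S <- sqrt((S + rnorm(length(S), 0, sigma))^2 +
              rnorm(length(S), 0, sigma)^2)
  }
  structure(list(data = array(S, dim = c(dim3, length(b))),
                 affine = phantom$affine, scheme = scheme),
            class = "alps_dwi")
}
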