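#' Spherical region-of-interest specification
#'
#' @param fiber One of `"projection"`, `"association"`, `"subcortical"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param center World coordinates (mm), length-3 numeric.
#' @param diameter Sphere diameter in mm (default 5, the study's ROI size).
#' @return An object of class `alps_roi`.
#' @export
roi_spec <- function(fiber, hemisphere, center, diameter = 5) {
  fiber <- match.arg(fiber, c("projection", "association", "subcortical"))
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  stopifnot(length(center) == 3L, all(is.finite(center)), diameter > 0)
  structure(list(fiber = fiber, hemisphere = hemisphere,
                 center = as.numeric(center), diameter = diameter),
            class = "alps_roi")
}

#' Voxel mask of a spherical ROI
#'
#' A voxel belongs to the sphere iff the world distance from its center to
#' the ROI center is at most `diameter / 2` (voxel-center inclusion, no
#' partial-volume weighting).
#'
#' @param roi An [roi_spec()].
#' @param dim Grid size `c(nx, ny, nz)`.
#' @param affine Voxel-to-world affine (0-based voxel indices).
#' @return A logical array of dimension `dim`.
#' @export
spherical_mask <- function(roi, dim, affine) {
  stopifnot(inherits(roi, "alps_roi"))
  ctr <- voxel_centers(dim, affine)
  d2 <- (ctr[, 1] - roi$center[1])^2 + (ctr[, 2] - roi$center[2])^2 +
        (ctr[, 3] - roi$center[3])^2
  inside <- d2 <= (roi$diameter / 2)^2
  if (!any(inside))
    stop(sprintf(paste0(
      "spherical ROI (%s, %s) at (%.1f, %.1f, %.1f) mm contains no voxel ",
      "center; the sphere is smaller than the voxel spacing at this ",
      "off-grid center - adjust the center or enlarge the diameter"),
      roi$fiber, roi$hemisphere, roi$center[1], roi$center[2],
      roi$center[3]))
  array(inside, dim = dim)
}

#' Locate fiber ROIs from a phantom label map
#'
#' ROI centers are placed at the world-space centroid of each fiber region's
#' label, one per fiber class and hemisphere. The study placed ROIs manually
#' on the color-FA map; centroid placement makes the step deterministic and
#' reproducible.
#'
#' @param labels Integer label array (codes from [region_labels()]).
#' @param affine Voxel-to-world affine.
#' @param hemisphere `"left"` or `"right"`.
#' @param fibers Fiber classes to locate.
#' @param diameter ROI diameter in mm.
#' @return A named list of [roi_spec()]s, one per fiber class.
#' @export
locate_rois <- function(labels, affine, hemisphere,
                        fibers = c("projection", "association",
                                   "subcortical"),
                        diameter = 5) {
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  lab <- region_labels()
  ctr <- voxel_centers(dim(labels), affine)
  out <- list()
  for (f in fibers) {
    code <- lab[[paste(f, hemisphere, sep = "_")]]
    idx <- which(labels == code)
    if (!length(idx))
      stop("label map has no '", f, "' region for the ", hemisphere,
           " hemisphere")
    out[[f]] <- roi_spec(f, hemisphere, colMeans(ctr[idx, , drop = FALSE]),
                         diameter = diameter)
  }
  out
}

#' Extract the ALPS index from a tensor field
#'
#' Averages the axis diffusivities over the projection and association ROIs
#' and forms the ALPS ratio
#' `mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)`:
#' x-axis (perivascular-direction) diffusivity in both fiber areas over the
#' fiber-transverse diffusivities (y in the projection area, z in the
#' association area). Voxels flagged by the fit (clamped eigenvalues or
#' floored signals) and voxels outside the fit mask are excluded from the ROI
#' means. A subcortical ROI, when present, is measured (mean Dxx) and
#' reported but does not enter the index.
#'
#' @param field An [fit_tensor()] result (or an `alps_phantom` with a `mask`;
#'   any object with `tensor`, `affine`, optional `mask`/`flags`).
#' @param rois A list of [roi_spec()]s containing at least `projection` and
#'   `association` entries (e.g. from [locate_rois()]).
#' @return An object of class `alps_measurement`: list with `hemisphere`,
#'   `dx_proj`, `dx_assoc`, `dy_proj`, `dz_assoc`, `alps_index`, `n_voxels`
#'   (named count per ROI) and, when a subcortical ROI was given,
#'   `dx_subcortical`.
#' @export
extract_alps <- function(field, rois) {
  if (is.null(rois$projection) || is.null(rois$association))
    stop("both a projection and an association ROI are required")
  ax <- axis_diffusivities(field)
  dim3 <- dim(ax$dxx)
  valid <- if (!is.null(field$mask)) field$mask else array(TRUE, dim = dim3)
  if (!is.null(field$flags)) valid <- valid & !field$flags
  roi_voxels <- function(roi) {
    m <- spherical_mask(roi, dim3, field$affine) & valid
    if (!any(m))
      stop("ROI (", roi$fiber, ", ", roi$hemisphere, ") contains no valid ",
           "voxel after excluding flagged/unmasked voxels")
    m
  }
  mp <- roi_voxels(rois$projection)
  ma <- roi_voxels(rois$association)
  dx_proj <- mean(ax$dxx[mp])
  dx_assoc <- mean(ax$dxx[ma])
  dy_proj <- mean(ax$dyy[mp])
  dz_assoc <- mean(ax$dzz[ma])
  n_voxels <- c(projection = sum(mp), association = sum(ma))
  out <- list(
    hemisphere = rois$projection$hemisphere,
    dx_proj = dx_proj, dx_assoc = dx_assoc,
    dy_proj = dy_proj, dz_assoc = dz_assoc,
    alps_index = mean(c(dx_proj, dx_assoc)) / mean(c(dy_proj, dz_assoc)),
    n_voxels = n_voxels
  )
  if (!is.null(rois$subcortical)) {
    ms <- roi_voxels(rois$subcortical)
    out$dx_subcortical <- mean(ax$dxx[ms])
    out$n_voxels <- c(n_voxels, subcortical = sum(ms))
  }
  structure(out, class = "alps_measurement")
}

#' @export
print.alps_measurement <- function(x, ...) {
  cat(sprintf(
    "ALPS measurement (%s): index = %.4f\n  Dxproj = %.4g  Dxassoc = %.4g  Dyproj = %.4g  Dzassoc = %.4g mm^2/s\n",
    x$hemisphere, x$alps_index, x$dx_proj, x$dx_assoc, x$dy_proj,
    x$dz_assoc))
  invisible(x)
}

#' Bilateral ALPS measurement for one subject
#'
#' Locates the fiber ROIs in each hemisphere from the label map and extracts
#' both ALPS indices.
#'
#' @param field An [fit_tensor()] result.
#' @param labels Integer label array matching the field's grid.
#' @param subject_id Optional identifier carried into the output row.
#' @param diameter ROI diameter in mm.
#' @return List with `left` and `right` [extract_alps()] measurements and
#'   `row`, a one-row data frame (subject_id, alps_left, alps_right).
#' @export
subject_alps <- function(field, labels, subject_id = NA_character_,
                         diameter = 5) {
  meas <- lapply(c(left = "left", right = "right"), function(h) {
    extract_alps(field, locate_rois(labels, field$affine, h,
                                    diameter = diameter))
  })
  list(left = meas$left, right = meas$right,
       row = data.frame(subject_id = subject_id,
                        alps_left = meas$left$alps_index,
                        alps_right = meas$right$alps_index,
                        stringsAsFactors = FALSE))
}
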