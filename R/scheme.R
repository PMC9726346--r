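#' Construct a diffusion acquisition scheme
#'
#' An acquisition scheme pairs every acquired volume with its diffusion
#' weighting: a b-value in s/mm^2 and a unit gradient direction. Volumes with
#' b = 0 carry the zero vector.
#'
#' @param bvals Numeric vector of non-negative b-values (s/mm^2), one per
#'   volume.
#' @param bvecs Numeric matrix with one row per volume and three columns
#'   (x, y, z). Rows belonging to nonzero b-values must have unit Euclidean
#'   norm (tolerance 1e-8); rows at b = 0 must be the zero vector.
#' @return An object of class `alps_scheme`: a list with elements `bvals`,
#'   `bvecs` and `n_b0` (the number of b = 0 volumes).
#' @seealso [build_default_scheme()], [read_bvalbvec()]
#' @export
acquisition_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L)
    stop("'bvecs' must have three columns (x, y, z)")
  if (length(bvals) != nrow(bvecs))
    stop("'bvals' and 'bvecs' describe different numbers of volumes (",
         length(bvals), " vs ", nrow(bvecs), ")")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  norms <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  if (any(abs(norms[nz] - 1) > 1e-8))
    stop("every gradient direction at b > 0 must have unit norm (within 1e-8)")
  if (any(norms[!nz] > 1e-8))
    stop("b = 0 volumes must carry the zero gradient vector")
  structure(
    list(bvals = bvals, bvecs = unname(bvecs), n_b0 = sum(!nz)),
    class = "alps_scheme"
  )
}

#' Default b = 0/600 acquisition scheme with 30 directions
#'
#' Builds the study protocol: `n_b0` unweighted volumes followed by `n_dirs`
#' diffusion-weighted volumes at b-value `b`, with gradient directions placed
#' by a spherical Fibonacci lattice. The lattice is a deterministic
#' low-discrepancy point set, so the scheme is reproducible bit for bit and
#' needs no optimisation step.
#'
#' @param n_dirs Number of diffusion-weighted directions (default 30).
#' @param n_b0 Number of b = 0 volumes (default 8).
#' @param b Nonzero b-value in s/mm^2 (default 600).
#' @return An `alps_scheme` with `n_b0 + n_dirs` volumes.
#' @examples
#' sch <- build_default_scheme()
#' length(sch$bvals)       # 38 volumes
#' sum(sch$bvals == 0)     # 8 b0 volumes
#' @export
build_default_scheme <- function(n_dirs = 30L, n_b0 = 8L, b = 600) {
  stopifnot(n_dirs >= 6L, n_b0 >= 1L, b > 0)
  i <- seq_len(n_dirs)
  z <- 1 - (2 * i - 1) / n_dirs
  phi <- pi * (1 + sqrt(5)) * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))  # guard against rounding
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  acquisition_scheme(c(rep(0, n_b0), rep(b, n_dirs)), bvecs)
}

#' @export
print.alps_scheme <- function(x, ...) {
  cat("Diffusion acquisition scheme:", length(x$bvals), "volumes\n")
  tb <- table(x$bvals)
  for (bv in names(tb))
    cat(sprintf("  b = %s s/mm^2: %d volume(s)\n", bv, tb[[bv]]))
  invisible(x)
}
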