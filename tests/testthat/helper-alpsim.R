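# Shared fixtures and independent oracles for the test suite.

tiny_layout <- function() default_layout(c(16L, 16L, 16L))

# Independent forward model: explicit per-volume quadratic form, no shared
# code with simulate_dwi().
forward_signal <- function(D, scheme, s0 = 100) {
  vapply(seq_along(scheme$bvals), function(i) {
    g <- scheme$bvecs[i, ]
    s0 * exp(-scheme$bvals[i] * drop(t(g) %*% D %*% g))
  }, numeric(1))
}

# Wrap a single voxel's signals as an alps_dwi on a 1x1x1 grid.
single_voxel_dwi <- function(signals, scheme) {
  structure(list(data = array(signals, dim = c(1, 1, 1, length(signals))),
                 affine = diag(4), scheme = scheme),
            class = "alps_dwi")
}

sym_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0) {
  matrix(c(dxx, dxy, dxz, dxy, dyy, dyz, dxz, dyz, dzz), 3, 3)
}

# Brute-force FA from eigenvalues.
brute_fa <- function(ev) {
  m <- mean(ev)
  sqrt(3 / 2) * sqrt(sum((ev - m)^2)) / sqrt(sum(ev^2))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
enum_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Analytic ALPS recomputed from a phantom's stored voxel tensors
# (independent of analytic_alps / extract_alps).
phantom_alps <- function(phantom, hemisphere) {
  lab <- region_labels()
  tmat <- matrix(phantom$tensor, ncol = 6)
  proj <- which(phantom$labels == lab[[paste0("projection_", hemisphere)]])
  asso <- which(phantom$labels == lab[[paste0("association_", hemisphere)]])
  mean(c(mean(tmat[proj, 1]), mean(tmat[asso, 1]))) /
    mean(c(mean(tmat[proj, 2]), mean(tmat[asso, 3])))
}
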