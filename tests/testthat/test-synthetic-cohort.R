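test_that("alps_to_tensors inverts the ALPS formula", {
  # isotropic transverse plane when the target is 1
  tt <- alps_to_tensors(1.0, 0.3e-3, 1.4e-3)
  expect_equal(tt$projection$eigenvalues[["x"]], 0.3e-3)
  expect_equal(tt$association$eigenvalues[["x"]], 0.3e-3)
  # direct arithmetic: lambda_x = target * baseline
  tt <- alps_to_tensors(1.5, 0.3e-3, 1.4e-3)
  expect_equal(tt$projection$eigenvalues[["x"]], 0.45e-3)
  expect_equal(analytic_alps(tt), 1.5)
  # fiber-parallel bound
  expect_error(alps_to_tensors(5.0, 0.3e-3, 1.4e-3), "bound")
  expect_error(alps_to_tensors(-1), "positive")
})

test_that("alps_to_tensors round trips across the working range", {
  set.seed(81)
  for (target in c(0.51, runif(40, 0.5, 4), 3.99)) {
    tt <- alps_to_tensors(target, 0.3e-3, 1.4e-3)
    expect_equal(analytic_alps(tt), target, tolerance = 1e-12)
    expect_equal(tt$projection$principal_axis, "z")
    expect_equal(tt$association$principal_axis, "y")
  }
})

test_that("phantom voxels carry the region tensors that realise the target", {
  lay <- tiny_layout()
  ph <- build_phantom(lay, left = alps_to_tensors(1.5),
                      right = alps_to_tensors(1.1))
  expect_equal(phantom_alps(ph, "left"), 1.5, tolerance = 1e-12)
  expect_equal(phantom_alps(ph, "right"), 1.1, tolerance = 1e-12)
  # CSF isotropic at 3.0e-3, background signal-free
  tmat <- matrix(ph$tensor, ncol = 6)
  csf <- which(ph$labels == region_labels()[["csf"]])
  expect_true(all(tmat[csf, 1:3] == 3.0e-3))
  expect_true(all(ph$s0[ph$labels == 0] == 0))
  expect_true(all(ph$s0[ph$labels > 0] > 0))
})

test_that("an isotropic tissue spec yields isotropic voxel tensors", {
  lay <- tiny_layout()
  iso <- function(region, axis) tissue_tensor_spec(
    region, c(x = 1e-3, y = 1e-3, z = 1e-3), axis)
  hemi <- list(projection = iso("projection", "z"),
               association = iso("association", "y"))
  ph <- build_phantom(lay, left = hemi, right = hemi,
                      subcortical = iso("subcortical", "x"),
                      csf_adc = 1e-3)
  tmat <- matrix(ph$tensor, ncol = 6)
  lab_vox <- which(ph$labels > 0)
  expect_true(all(tmat[lab_vox, 1] == tmat[lab_vox, 2]))
  expect_true(all(tmat[lab_vox, 2] == tmat[lab_vox, 3]))
})

test_that("layouts are mirror-symmetric about the mid-sagittal plane", {
  for (lay in list(default_layout(), tiny_layout())) {
    lab <- region_labels()
    ctr <- alpsim:::voxel_centers(lay$dim, lay$affine)
    for (reg in c("projection", "association", "subcortical")) {
      cl <- colMeans(ctr[which(lay$labels == lab[[paste0(reg, "_left")]]), ,
                         drop = FALSE])
      cr <- colMeans(ctr[which(lay$labels == lab[[paste0(reg, "_right")]]), ,
                         drop = FALSE])
      expect_equal(cl * c(-1, 1, 1), cr, tolerance = 1e-12)
    }
  }
})

test_that("noiseless signals follow the closed-form tensor model", {
  lay <- tiny_layout()
  sch <- build_default_scheme()
  ph <- build_phantom(lay, left = alps_to_tensors(1.2),
                      right = alps_to_tensors(1.2))
  dwi <- simulate_dwi(ph, sch, snr = Inf)
  # b = 0 equals S0 exactly
  b0 <- which(ph$s0 > 0)
  expect_equal(dwi$data[, , , 1][b0], ph$s0[b0], tolerance = 0)
  # isotropic voxel at b = 600: S/S0 = exp(-0.6)
  iso <- function(region, axis) tissue_tensor_spec(
    region, c(x = 1e-3, y = 1e-3, z = 1e-3), axis)
  hemi <- list(projection = iso("projection", "z"),
               association = iso("association", "y"))
  ph_iso <- build_phantom(lay, left = hemi, right = hemi,
                          subcortical = iso("subcortical", "x"),
                          csf_adc = 1e-3)
  dwi_iso <- simulate_dwi(ph_iso, sch, snr = Inf)
  vox <- which(ph_iso$labels == region_labels()[["projection_left"]])[1]
  ijk <- arrayInd(vox, lay$dim)
  expect_equal(dwi_iso$data[ijk[1], ijk[2], ijk[3], 38] /
                 ph_iso$s0[vox], exp(-0.6), tolerance = 1e-12)
  expect_error(simulate_dwi(ph, sch, snr = -1), "positive")
})

test_that("noisy acquisitions are seeded and bit-reproducible", {
  lay <- tiny_layout()
  sch <- build_default_scheme()
  ph <- build_phantom(lay, left = alps_to_tensors(1.2),
                      right = alps_to_tensors(1.2))
  a <- simulate_dwi(ph, sch, snr = 20, seed = 7)
  b <- simulate_dwi(ph, sch, snr = 20, seed = 7)
  expect_identical(a$data, b$data)
  c2 <- simulate_dwi(ph, sch, snr = 20, seed = 8)
  expect_false(identical(a$data, c2$data))
})

test_that("Rician magnitude noise has non-negative bias at SNR 5", {
  lay <- default_layout(c(16L, 16L, 8L))
  sch <- acquisition_scheme(c(0, 600), rbind(c(0, 0, 0), c(1, 0, 0)))
  ph <- build_phantom(lay, left = alps_to_tensors(1.2),
                      right = alps_to_tensors(1.2))
  noiseless <- simulate_dwi(ph, sch, snr = Inf)
  vox <- which(ph$labels == region_labels()[["projection_left"]])
  ijk <- arrayInd(vox, lay$dim)
  acc0 <- acc1 <- 0
  n_mc <- 300
  for (r in seq_len(n_mc)) {
    noisy <- simulate_dwi(ph, sch, snr = 5, seed = 1000 + r)
    acc0 <- acc0 + mean(noisy$data[cbind(ijk, 1)])
    acc1 <- acc1 + mean(noisy$data[cbind(ijk, 2)])
  }
  expect_gte(acc0 / n_mc, mean(noiseless$data[cbind(ijk, 1)]))
  expect_gte(acc1 / n_mc, mean(noiseless$data[cbind(ijk, 2)]))
})

test_that("cohort sampling reproduces the configured structure", {
  cfg <- default_cohort_config()
  coh <- sample_cohort(cfg, seed = 3)
  df <- coh$subjects
  expect_equal(nrow(df), 55L)
  expect_equal(sum(df$group == "ASD"), 30L)
  expect_equal(sum(df$group == "control"), 25L)
  # the CSV sidecar carries one row per enrolled subject
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  expect_equal(nrow(utils::read.csv(f)), 55L)
  expect_named(utils::read.csv(f),
               c("subject_id", "group", "age_months", "ga_weeks", "sex",
                 "alps_true_left", "alps_true_right"))
  # sampling is a pure function of (config, seed)
  expect_identical(df, sample_cohort(cfg, seed = 3)$subjects)
  expect_false(identical(df, sample_cohort(cfg, seed = 4)$subjects))
  # per-subject tensor specs realise the drawn ALPS exactly
  for (s in coh$truth[c(1, 17, 40)]) {
    expect_equal(analytic_alps(s$left), s$alps_true[["left"]],
                 tolerance = 1e-12)
    expect_equal(analytic_alps(s$right), s$alps_true[["right"]],
                 tolerance = 1e-12)
  }
  expect_true(all(df$alps_true_left > 0.5 & df$alps_true_right > 0.5))
})

test_that("cohort means and correlations track the configuration", {
  cfg <- default_cohort_config()
  coh <- sample_cohort(cfg, seed = 11)
  asd <- coh$subjects[coh$subjects$group == "ASD", ]
  # CLT bound: sample mean within 3 SD / sqrt(n) of the configured mean
  expect_lt(abs(mean(asd$alps_true_left) - 1.02), 3 * 0.12 / sqrt(30))
  expect_lt(abs(mean(asd$alps_true_right) - 1.03), 3 * 0.12 / sqrt(30))
  expect_lt(abs(mean(asd$age_months) - 47.83), 3 * 15.56 / sqrt(30))
  # zero correlation: independence at large n
  cfg0 <- default_cohort_config()
  cfg0$groups$control <- NULL
  cfg0$groups$ASD$n <- 2000L
  cfg0$groups$ASD$rho_left <- 0
  big <- sample_cohort(cfg0, seed = 5)$subjects
  expect_lt(abs(cor(big$age_months, big$alps_true_left)), 0.05)
  # positive configured correlation shows up in the sample
  cfg1 <- default_cohort_config()
  cfg1$groups$control <- NULL
  cfg1$groups$ASD$n <- 2000L
  big1 <- sample_cohort(cfg1, seed = 6)$subjects
  expect_equal(cor(big1$age_months, big1$alps_true_left), sqrt(0.4658),
               tolerance = 0.05)
})

test_that("cohort configs are validated", {
  cfg <- default_cohort_config()
  cfg$groups$ASD$n <- 1L
  expect_error(sample_cohort(cfg, seed = 1), "at least 2")
  cfg <- default_cohort_config()
  cfg$groups$ASD$alps_left[["sd"]] <- 0
  expect_error(sample_cohort(cfg, seed = 1), "SD must be positive")
  cfg <- default_cohort_config()
  cfg$groups$control$rho_right <- 1
  expect_error(sample_cohort(cfg, seed = 1), "below 1")
})
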