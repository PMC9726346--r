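#' Default run configuration
#'
#' Bundles the cohort configuration, phantom layout parameters, acquisition
#' scheme settings, SNR, statistics family and seed for a full
#' simulate-fit-index-stats run at the study conditions.
#'
#' @param seed Integer seed driving every random draw of the run.
#' @param dim,voxel Phantom grid size and voxel dimensions (mm).
#' @param snr Simulated b = 0 signal-to-noise ratio.
#' @param cohort An [default_cohort_config()]-style configuration.
#' @param family Bonferroni comparison family for [compare_groups()].
#' @return A list of class `alps_run_config`.
#' @export
default_run_config <- function(seed = 1L,
                               dim = c(64L, 64L, 16L),
                               voxel = c(1.875, 1.875, 2.5),
                               snr = 40,
                               cohort = default_cohort_config(snr = snr),
                               family = c("alps_left", "alps_right",
                                          "age_months")) {
  structure(list(seed = as.integer(seed), dim = as.integer(dim),
                 voxel = voxel, snr = snr, cohort = cohort, family = family),
            class = "alps_run_config")
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass_deep(config), f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

subject_seeds <- function(seed, n) {
  # Deterministic per-subject substreams: one top-level draw of n seeds so
  # subjects are reproducible regardless of processing order.
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Image a cohort: phantom, acquisition, tensor fit, ALPS extraction
#'
#' Runs the full per-subject imaging chain for every subject of a sampled
#' cohort and returns the subject table augmented with the estimated
#' bilateral ALPS indices.
#'
#' @param cohort An [sample_cohort()] result.
#' @param layout An [default_layout()]; built from `dim`/`voxel` when `NULL`.
#' @param scheme An [acquisition_scheme()]; the default b = 0/600 protocol
#'   when `NULL`.
#' @param snr Acquisition SNR (defaults to the cohort config's).
#' @param seed Seed spawning the per-subject noise substreams.
#' @param verbose Print one line per subject.
#' @return The cohort's subject data frame with columns `alps_left`,
#'   `alps_right` (estimated) appended, plus attribute `"measurements"`
#'   holding the per-hemisphere detail rows.
#' @export
estimate_cohort_alps <- function(cohort, layout = NULL, scheme = NULL,
                                 snr = cohort$config$snr, seed = 1L,
                                 verbose = FALSE) {
  stopifnot(inherits(cohort, "alps_cohort"))
  if (is.null(layout)) layout <- default_layout()
  if (is.null(scheme)) scheme <- build_default_scheme()
  n <- nrow(cohort$subjects)
  seeds <- subject_seeds(seed, n)
  est_l <- numeric(n)
  est_r <- numeric(n)
  detail <- vector("list", n)
  for (i in seq_len(n)) {
    subj <- cohort$truth[[i]]
    phantom <- build_phantom(layout, subject = subj)
    dwi <- simulate_dwi(phantom, scheme, snr = snr, seed = seeds[i])
    field <- fit_tensor(dwi, mask = phantom$s0 > 0)
    sa <- subject_alps(field, layout$labels, subject_id = subj$subject_id)
    est_l[i] <- sa$left$alps_index
    est_r[i] <- sa$right$alps_index
    detail[[i]] <- do.call(rbind, lapply(list(sa$left, sa$right),
      function(m) data.frame(
        subject_id = subj$subject_id, hemisphere = m$hemisphere,
        dx_proj = m$dx_proj, dx_assoc = m$dx_assoc, dy_proj = m$dy_proj,
        dz_assoc = m$dz_assoc, alps_index = m$alps_index,
        n_voxels = sum(m$n_voxels), stringsAsFactors = FALSE)))
    if (verbose)
      message(sprintf("  [%d/%d] %s: left %.3f (true %.3f) right %.3f (true %.3f)",
                      i, n, subj$subject_id, est_l[i],
                      subj$alps_true[["left"]], est_r[i],
                      subj$alps_true[["right"]]))
  }
  out <- cohort$subjects
  out$alps_left <- est_l
  out$alps_right <- est_r
  attr(out, "measurements") <- do.call(rbind, detail)
  out
}

#' Run the full pipeline: simulate, fit, index, stats
#'
#' Samples the cohort, images every subject, extracts bilateral ALPS
#' indices, runs the group comparison and age correlations, and writes the
#' declared artifacts plus a run manifest. Identical config and seed yield
#' byte-identical subject CSV and stats JSON.
#'
#' @param config An [default_run_config()].
#' @param out_dir Output directory (created).
#' @param keep_volumes Also write each subject's simulated DWI series and
#'   gradient tables (large; off by default).
#' @param verbose Log stage progress to stderr.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config = default_run_config(), out_dir,
                    keep_volumes = FALSE, verbose = TRUE) {
  stopifnot(inherits(config, "alps_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]
  layout <- default_layout(config$dim, config$voxel)
  scheme <- build_default_scheme()

  t0 <- tic()
  say("[simulate] sampling cohort (seed %d)", config$seed)
  cohort <- sample_cohort(config$cohort, seed = config$seed)
  subjects_csv <- file.path(out_dir, "subjects.csv")
  write_cohort_csv(cohort, subjects_csv)
  jsonlite::write_json(
    lapply(cohort$truth, function(s) list(
      subject_id = s$subject_id, group = s$group,
      age_months = s$age_months, ga_weeks = s$ga_weeks, sex = s$sex,
      alps_true = as.list(s$alps_true))),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_nifti(layout$labels, layout$affine,
              file.path(out_dir, "labels.nii.gz"))
  write_bvalbvec(scheme, file.path(out_dir, "dwi"))
  stages$simulate <- list(status = "ok", seconds = tic() - t0,
                          n_subjects = nrow(cohort$subjects))

  t0 <- tic()
  say("[fit+index] imaging %d subjects at SNR %g on a %s grid",
      nrow(cohort$subjects), config$snr, paste(config$dim, collapse = "x"))
  if (keep_volumes) {
    seeds <- subject_seeds(config$seed, nrow(cohort$subjects))
    for (i in seq_len(nrow(cohort$subjects))) {
      phantom <- build_phantom(layout, subject = cohort$truth[[i]])
      dwi <- simulate_dwi(phantom, scheme, snr = config$snr, seed = seeds[i])
      write_nifti(dwi$data, dwi$affine,
                  file.path(out_dir, paste0("dwi_",
                    cohort$truth[[i]]$subject_id, ".nii.gz")))
    }
  }
  est <- estimate_cohort_alps(cohort, layout = layout, scheme = scheme,
                              snr = config$snr, seed = config$seed,
                              verbose = FALSE)
  estimates_csv <- file.path(out_dir, "alps_estimates.csv")
  utils::write.csv(est, estimates_csv, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(attr(est, "measurements"),
                   file.path(out_dir, "measurements.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  stages$imaging <- list(status = "ok", seconds = tic() - t0)

  t0 <- tic()
  say("[stats] group comparison and age correlations")
  comp <- compare_groups(est, family = config$family)
  cors <- age_correlations(est)
  files <- report_stats(comp, cors, file.path(out_dir, "stats"))
  stages$stats <- list(status = "ok", seconds = tic() - t0)

  manifest <- list(
    package_version = as.character(utils::packageVersion("alpsim")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    outputs = c(subjects = subjects_csv, estimates = estimates_csv,
                measurements = file.path(out_dir, "measurements.csv"),
                labels = file.path(out_dir, "labels.nii.gz"),
                ground_truth = file.path(out_dir, "ground_truth.json"),
                files))
  missing <- !file.exists(manifest$outputs)
  if (any(missing))
    stop("pipeline finished but declared outputs are missing: ",
         paste(manifest$outputs[missing], collapse = ", "))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build a bundled test fixture configuration
#'
#' `"smoke"`: 4 subjects (2 per group) on a 16 x 16 x 16 grid, for fast
#' end-to-end checks. `"study"`: the full study conditions (30 + 25 subjects,
#' 64 x 64 x 16 grid). Both carry a fixed seed; the checksum of the cohort
#' CSV the config generates is included so reruns can be verified.
#'
#' @param scale `"smoke"` or `"study"`.
#' @param seed Seed stored in the configuration.
#' @return List with `config` (an `alps_run_config`) and `cohort_md5`.
#' @export
make_fixture <- function(scale = c("smoke", "study"), seed = 1L) {
  scale <- match.arg(scale)
  config <- if (scale == "smoke") {
    cc <- default_cohort_config()
    cc$groups$ASD$n <- 2L
    cc$groups$control$n <- 2L
    default_run_config(seed = seed, dim = c(16L, 16L, 16L), cohort = cc)
  } else {
    default_run_config(seed = seed)
  }
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cohort_csv(sample_cohort(config$cohort, seed = config$seed), f)
  list(config = config, cohort_md5 = unname(tools::md5sum(f)))
}

# --- File-interface stage functions -----------------------------------------
# Each stage communicates with the others only through the files it declares;
# the CLI wraps these one-to-one.

#' Simulation stage: write DWI volumes, labels, gradients and cohort table
#'
#' @param config An [default_run_config()].
#' @param dir Stage output directory.
#' @return Paths written, invisibly.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- default_layout(config$dim, config$voxel)
  scheme <- build_default_scheme()
  cohort <- sample_cohort(config$cohort, seed = config$seed)
  write_cohort_csv(cohort, file.path(dir, "subjects.csv"))
  write_nifti(layout$labels, layout$affine, file.path(dir, "labels.nii.gz"))
  write_bvalbvec(scheme, file.path(dir, "dwi"))
  seeds <- subject_seeds(config$seed, nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    subj <- cohort$truth[[i]]
    phantom <- build_phantom(layout, subject = subj)
    dwi <- simulate_dwi(phantom, scheme, snr = config$snr, seed = seeds[i])
    write_nifti(dwi$data, dwi$affine,
                file.path(dir, paste0("dwi_", subj$subject_id, ".nii.gz")))
  }
  invisible(dir)
}

#' Tensor-fit stage: read DWI series, write tensor and map volumes
#'
#' @param dir Directory holding `stage_simulate()` outputs.
#' @return Paths written, invisibly.
#' @export
stage_fit <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  labels <- read_nifti(file.path(dir, "labels.nii.gz"))
  brain_mask <- labels$data > 0
  for (id in subjects$subject_id) {
    dwi <- read_dwi(file.path(dir, paste0("dwi_", id, ".nii.gz")),
                    file.path(dir, "dwi.bval"), file.path(dir, "dwi.bvec"))
    field <- fit_tensor(dwi, mask = brain_mask)
    write_nifti(field$tensor, field$affine,
                file.path(dir, paste0("tensor_", id, ".nii.gz")))
    write_nifti(field$fa, field$affine,
                file.path(dir, paste0("fa_", id, ".nii.gz")))
    write_nifti(field$md, field$affine,
                file.path(dir, paste0("md_", id, ".nii.gz")))
    write_nifti(color_fa(field), field$affine,
                file.path(dir, paste0("colorfa_", id, ".nii.gz")))
    write_nifti(field$flags + 0L, field$affine,
                file.path(dir, paste0("flags_", id, ".nii.gz")))
    write_nifti(field$mask + 0L, field$affine,
                file.path(dir, paste0("mask_", id, ".nii.gz")))
  }
  invisible(dir)
}

#' ALPS-index stage: read tensor volumes and labels, write measurement CSVs
#'
#' @param dir Directory holding `stage_fit()` outputs.
#' @return Paths written, invisibly.
#' @export
stage_index <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  labels <- read_nifti(file.path(dir, "labels.nii.gz"))
  lab_arr <- array(as.integer(round(labels$data)), dim = dim(labels$data))
  rows <- list()
  detail <- list()
  for (id in subjects$subject_id) {
    tens <- read_nifti(file.path(dir, paste0("tensor_", id, ".nii.gz")))
    flags <- read_nifti(file.path(dir, paste0("flags_", id, ".nii.gz")))
    mask <- read_nifti(file.path(dir, paste0("mask_", id, ".nii.gz")))
    field <- list(tensor = tens$data, affine = tens$affine,
                  flags = flags$data > 0, mask = mask$data > 0)
    sa <- subject_alps(field, lab_arr, subject_id = id)
    rows[[id]] <- sa$row
    detail[[id]] <- do.call(rbind, lapply(list(sa$left, sa$right),
      function(m) data.frame(
        subject_id = id, hemisphere = m$hemisphere, dx_proj = m$dx_proj,
        dx_assoc = m$dx_assoc, dy_proj = m$dy_proj, dz_assoc = m$dz_assoc,
        alps_index = m$alps_index, n_voxels = sum(m$n_voxels))))
  }
  est <- merge(subjects, do.call(rbind, rows), by = "subject_id", sort = FALSE)
  utils::write.csv(est, file.path(dir, "alps_estimates.csv"),
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(do.call(rbind, c(detail, list(make.row.names = FALSE))),
                   file.path(dir, "measurements.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Statistics stage: read the estimate CSV, write report tables and JSON
#'
#' @param dir Directory holding `stage_index()` outputs.
#' @param family Bonferroni comparison family.
#' @return Paths written, invisibly.
#' @export
stage_stats <- function(dir, family = c("alps_left", "alps_right",
                                        "age_months")) {
  est <- utils::read.csv(file.path(dir, "alps_estimates.csv"))
  comp <- compare_groups(est, family = family)
  cors <- age_correlations(est)
  report_stats(comp, cors, file.path(dir, "stats"))
  invisible(dir)
}

#' @export
print.alps_run_config <- function(x, ...) {
  ns <- vapply(x$cohort$groups, function(g) as.integer(g$n), integer(1))
  cat(sprintf(
    "ALPS run config: %s subjects (%s), grid %s, SNR %g, seed %d\n",
    sum(ns), paste(sprintf("%s n=%d", names(ns), ns), collapse = ", "),
    paste(x$dim, collapse = "x"), x$snr, x$seed))
  invisible(x)
}
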