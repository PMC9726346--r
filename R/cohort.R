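#' Default cohort configuration
#'
#' The study conditions: an autism (ASD) group of 30 children and a control
#' group of 25, with per-hemisphere ALPS means/SDs, age and gestational-age
#' distributions, male fractions, and age-ALPS population correlations
#' (rho = sqrt of the reported R-squared, positive in both groups). Ages are
#' in months, gestational age in weeks.
#'
#' @param snr Signal-to-noise ratio used when the cohort is imaged.
#' @param seed Optional default seed stored in the config.
#' @return A list of class `alps_cohort_config` with per-group parameter
#'   lists (`groups`), `snr`, `alps_min` (truncation bound) and `seed`.
#' @export
default_cohort_config <- function(snr = 40, seed = NULL) {
  groups <- list(
    ASD = list(
      n = 30L,
      alps_left  = c(mean = 1.02, sd = 0.12),
      alps_right = c(mean = 1.03, sd = 0.12),
      age        = c(mean = 47.83, sd = 15.56),
      ga         = c(mean = 39.67, sd = 0.99),
      male_frac  = 0.80,
      rho_left   = sqrt(0.4658),
      rho_right  = sqrt(0.441)
    ),
    control = list(
      n = 25L,
      alps_left  = c(mean = 1.27, sd = 0.25),
      alps_right = c(mean = 1.32, sd = 0.20),
      age        = c(mean = 44.80, sd = 15.01),
      ga         = c(mean = 39.48, sd = 1.16),
      male_frac  = 0.72,
      rho_left   = sqrt(0.3028),
      rho_right  = sqrt(0.3709)
    )
  )
  structure(list(groups = groups, snr = snr, alps_min = 0.5, seed = seed),
            class = "alps_cohort_config")
}

validate_cohort_config <- function(config) {
  if (!is.list(config$groups) || !length(config$groups))
    stop("config must define at least one group")
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    if (is.null(g$n) || g$n < 2L)
      stop("group '", gname, "': n must be at least 2")
    for (f in c("alps_left", "alps_right", "age", "ga")) {
      if (g[[f]][["sd"]] <= 0)
        stop("group '", gname, "': ", f, " SD must be positive")
    }
    for (f in c("rho_left", "rho_right")) {
      if (abs(g[[f]]) >= 1)
        stop("group '", gname, "': |", f, "| must be below 1")
    }
    if (g$male_frac < 0 || g$male_frac > 1)
      stop("group '", gname, "': male_frac must lie in [0, 1]")
  }
  if (!is.numeric(config$snr) || config$snr <= 0)
    stop("config snr must be positive")
  invisible(config)
}

# Truncated draws: redraw offending entries until all satisfy the bound.
redraw_above <- function(x, draw, bound) {
  while (any(bad <- x <= bound))
    x[bad] <- draw(sum(bad))
  x
}

#' Sample a synthetic cohort with known ground truth
#'
#' Draws per-subject (age, ALPS) pairs from a bivariate normal with the
#' configured means, SDs and age-ALPS correlation rho; both hemispheres share
#' the subject's age. ALPS draws are truncated to values above
#' `config$alps_min` by redrawing the hemisphere residual (the bound sits
#' about 3 SD below every configured mean, so truncation is essentially
#' inactive). Gestational age and sex are drawn independently. Each subject
#' also carries the projection/association tensor specs realising its true
#' ALPS (via [alps_to_tensors()]), so phantoms can be built directly.
#'
#' @param config An [default_cohort_config()]-style configuration.
#' @param seed Integer seed; defaults to `config$seed`. The draw is a pure
#'   function of (config, seed).
#' @return An object of class `alps_cohort`: list with `subjects` (data frame
#'   with columns subject_id, group, age_months, ga_weeks, sex,
#'   alps_true_left, alps_true_right), `truth` (per-subject list of
#'   `alps_subject_truth` objects holding the hemisphere tensor specs) and
#'   `config`.
#' @export
sample_cohort <- function(config = default_cohort_config(),
                          seed = config$seed) {
  validate_cohort_config(config)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    n <- as.integer(g$n)
    age <- redraw_above(rnorm(n, g$age[["mean"]], g$age[["sd"]]),
                        function(k) rnorm(k, g$age[["mean"]], g$age[["sd"]]),
                        0)
    z_age <- (age - g$age[["mean"]]) / g$age[["sd"]]
    draw_hemi <- function(ms, rho) {
      val <- ms[["mean"]] + ms[["sd"]] *
        (rho * z_age + sqrt(1 - rho^2) * rnorm(n))
      while (any(bad <- val <= config$alps_min)) {
        val[bad] <- ms[["mean"]] + ms[["sd"]] *
          (rho * z_age[bad] + sqrt(1 - rho^2) * rnorm(sum(bad)))
      }
      val
    }
    alps_l <- draw_hemi(g$alps_left, g$rho_left)
    alps_r <- draw_hemi(g$alps_right, g$rho_right)
    ga <- rnorm(n, g$ga[["mean"]], g$ga[["sd"]])
    sex <- ifelse(runif(n) < g$male_frac, "male", "female")
    ids <- sprintf("%s%02d", gname, seq_len(n))
    rows[[gname]] <- data.frame(
      subject_id = ids, group = gname, age_months = age, ga_weeks = ga,
      sex = sex, alps_true_left = alps_l, alps_true_right = alps_r,
      stringsAsFactors = FALSE)
    truth[[gname]] <- lapply(seq_len(n), function(i) {
      structure(list(
        subject_id = ids[i], group = gname, age_months = age[i],
        ga_weeks = ga[i], sex = sex[i],
        alps_true = c(left = alps_l[i], right = alps_r[i]),
        left = alps_to_tensors(alps_l[i]),
        right = alps_to_tensors(alps_r[i])
      ), class = "alps_subject_truth")
    })
  }
  structure(list(
    subjects = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    truth = do.call(c, unname(truth)),
    config = config
  ), class = "alps_cohort")
}

#' Write a cohort's subject table to CSV
#'
#' Comma-separated, header row, UTF-8; columns subject_id, group, age_months,
#' ga_weeks, sex, alps_true_left, alps_true_right.
#'
#' @param cohort An [sample_cohort()] result (or its `subjects` data frame).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- if (inherits(cohort, "alps_cohort")) cohort$subjects else cohort
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}
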