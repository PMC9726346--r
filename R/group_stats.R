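#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The exact null
#' distribution is used when `n1 * n2 <= 400` and the pooled data are
#' tie-free; otherwise the normal approximation with midrank tie correction
#' and continuity correction. `mode` can force either route (forcing the
#' exact test on tied data falls back to the approximation with a warning).
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @return List with `U` (the U statistic of `x`), `p` (two-sided), `n1`,
#'   `n2` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) * length(y) <= 400) && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties) {
    warning("ties present; exact Mann-Whitney p is undefined, ",
            "using the normal approximation")
    exact <- FALSE
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value,
       n1 = length(x), n2 = length(y),
       method = if (exact) "exact" else "normal approximation")
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric samples of equal length, n >= 3, each with nonzero
#'   variance.
#' @param group,hemisphere Optional labels carried into the result.
#' @return List of class `alps_correlation` with `r`, `r_squared`, `p`
#'   (two-sided, from the t distribution with n - 2 df), `n`, and any
#'   labels.
#' @export
pearson_correlation <- function(x, y, group = NA_character_,
                                hemisphere = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop("Pearson correlation requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a sample has zero variance")
  ht <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  structure(list(group = group, hemisphere = hemisphere, r = r,
                 r_squared = r^2, p = ht$p.value, n = length(x)),
            class = "alps_correlation")
}

two_group_split <- function(records) {
  groups <- unique(records$group)
  if (length(groups) != 2L)
    stop("records must contain exactly two groups (found ",
         length(groups), ")")
  split(records, factor(records$group, levels = groups))
}

#' Compare variables between the two groups
#'
#' Per continuous variable: group means and SDs, two-sided Mann-Whitney U
#' test, and a significance flag at the Bonferroni-adjusted threshold
#' `alpha / length(family)` (default family left ALPS, right ALPS and age,
#' giving 0.05 / 3 ~ .017). The binary variable `sex` is compared by a
#' two-sided Fisher exact test on the 2 x 2 table by default
#' (`sex_test = "mann_whitney"` ranks a 0/1 coding instead); its summary
#' columns report the male count and percentage.
#'
#' @param records Data frame with a `group` column (exactly two groups) and
#'   the requested variables.
#' @param variables Character vector of columns to compare.
#' @param family Comparison family defining the Bonferroni divisor.
#' @param alpha Family-wise error rate (default 0.05).
#' @param sex_test `"fisher"` or `"mann_whitney"`.
#' @return A data frame of class `alps_group_comparison` with one row per
#'   variable: group summaries, `U`, `p`, `threshold`, `significant`.
#' @export
compare_groups <- function(records,
                           variables = c("alps_left", "alps_right",
                                         "age_months", "ga_weeks", "sex"),
                           family = c("alps_left", "alps_right",
                                      "age_months"),
                           alpha = 0.05,
                           sex_test = c("fisher", "mann_whitney")) {
  sex_test <- match.arg(sex_test)
  gs <- two_group_split(records)
  gnames <- names(gs)
  threshold <- alpha / length(family)
  rows <- lapply(variables, function(v) {
    if (!v %in% names(records))
      stop("variable '", v, "' not found in records")
    if (v == "sex") {
      male <- vapply(gs, function(d) sum(d$sex == "male"), integer(1))
      n <- vapply(gs, nrow, integer(1))
      if (sex_test == "fisher") {
        tab <- rbind(male, n - male)
        p <- stats::fisher.test(tab)$p.value
        u <- NA_real_
      } else {
        mw <- mann_whitney_u(as.numeric(gs[[1]]$sex == "male"),
                             as.numeric(gs[[2]]$sex == "male"),
                             mode = "approx")
        p <- mw$p; u <- mw$U
      }
      data.frame(variable = "sex",
                 mean_1 = male[1], sd_1 = 100 * male[1] / n[1],
                 mean_2 = male[2], sd_2 = 100 * male[2] / n[2],
                 U = u, p = p, stringsAsFactors = FALSE)
    } else {
      x1 <- gs[[1]][[v]]; x2 <- gs[[2]][[v]]
      mw <- mann_whitney_u(x1, x2)
      data.frame(variable = v,
                 mean_1 = mean(x1), sd_1 = stats::sd(x1),
                 mean_2 = mean(x2), sd_2 = stats::sd(x2),
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$threshold <- threshold
  out$significant <- out$p < threshold
  attr(out, "groups") <- gnames
  class(out) <- c("alps_group_comparison", class(out))
  out
}

#' Age-ALPS Pearson correlations per group and hemisphere
#'
#' Computes the four correlations (each group x left/right hemisphere)
#' between age and the ALPS index. Strata with fewer than three subjects or
#' zero variance are skipped with a warning.
#'
#' @param records Data frame with columns `group`, `age_months`, `alps_left`,
#'   `alps_right`.
#' @param alps_cols Names of the left/right ALPS columns.
#' @return Data frame with columns group, hemisphere, r, r_squared, p, n.
#'   The per-stratum scatter data are attached as attribute `"scatter"` for
#'   plotting.
#' @export
age_correlations <- function(records,
                             alps_cols = c(left = "alps_left",
                                           right = "alps_right")) {
  rows <- list()
  scatter <- list()
  for (g in unique(records$group)) {
    d <- records[records$group == g, ]
    for (h in names(alps_cols)) {
      y <- d[[alps_cols[[h]]]]
      if (nrow(d) < 3L || stats::sd(d$age_months) == 0 || stats::sd(y) == 0) {
        warning("skipping age correlation for ", g, "/", h,
                ": fewer than 3 subjects or zero variance")
        next
      }
      ct <- pearson_correlation(d$age_months, y, group = g, hemisphere = h)
      rows[[paste(g, h)]] <- data.frame(
        group = g, hemisphere = h, r = ct$r, r_squared = ct$r_squared,
        p = ct$p, n = ct$n, stringsAsFactors = FALSE)
      scatter[[paste(g, h)]] <- data.frame(
        group = g, hemisphere = h, age_months = d$age_months, alps = y,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else data.frame(group = character(), hemisphere = character(),
                         r = numeric(), r_squared = numeric(), p = numeric(),
                         n = integer())
  attr(out, "scatter") <- if (length(scatter))
    do.call(rbind, c(scatter, list(make.row.names = FALSE))) else NULL
  out
}

#' Render a p-value in table style
#'
#' Three decimals with the leading zero dropped; values below 0.0005 render
#' as `"<.001"`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @examples
#' format_p(c(0.0003, 0.52))  # "<.001" ".520"
#' @export
format_p <- function(p) {
  out <- sub("^0\\.", ".", sprintf("%.3f", p))
  out[p < 0.0005] <- "<.001"
  out[is.na(p)] <- ""
  out
}

format_mean_sd <- function(m, s) sprintf("%.2f ± %.2f", m, s)

#' Write demographic and ALPS comparison tables and a stats JSON
#'
#' Renders the group comparison in the style of the study's tables
#' ("mean +/- SD" cells, male counts with percentages, p-values to three
#' decimals with `"<.001"` below 0.0005) and writes a machine-readable JSON
#' with the raw numbers.
#'
#' @param comparisons An [compare_groups()] result (possibly empty).
#' @param correlations An [age_correlations()] result, or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
report_stats <- function(comparisons, correlations = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gnames <- attr(comparisons, "groups")
  if (is.null(gnames)) gnames <- c("group1", "group2")
  render <- function(df) {
    if (!nrow(df))
      return(data.frame(variable = character(), g1 = character(),
                        g2 = character(), p = character()))
    cell <- function(m, s, v)
      ifelse(v == "sex", sprintf("%d (%.2f %%)", as.integer(m), s),
             format_mean_sd(m, s))
    out <- data.frame(variable = df$variable,
                      g1 = cell(df$mean_1, df$sd_1, df$variable),
                      g2 = cell(df$mean_2, df$sd_2, df$variable),
                      p = format_p(df$p), stringsAsFactors = FALSE)
    names(out) <- c("variable", gnames[1], gnames[2], "P value")
    out
  }
  demo_vars <- intersect(c("age_months", "ga_weeks", "sex"),
                         comparisons$variable)
  alps_vars <- intersect(c("alps_left", "alps_right"), comparisons$variable)
  files <- c(
    demographics = file.path(dir, "demographics.csv"),
    alps = file.path(dir, "alps_comparison.csv"),
    correlations = file.path(dir, "age_correlations.csv"),
    json = file.path(dir, "stats.json"))
  utils::write.csv(render(comparisons[comparisons$variable %in% demo_vars, ]),
                   files[["demographics"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(render(comparisons[comparisons$variable %in% alps_vars, ]),
                   files[["alps"]], row.names = FALSE, fileEncoding = "UTF-8")
  cor_df <- if (is.null(correlations))
    data.frame(group = character(), hemisphere = character(), r = numeric(),
               r_squared = numeric(), p = numeric(), n = integer())
  else correlations
  cor_out <- cor_df
  if (nrow(cor_out)) cor_out$p <- format_p(cor_out$p)
  utils::write.csv(cor_out, files[["correlations"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  payload <- list(
    groups = gnames,
    comparisons = as.data.frame(unclass(comparisons),
                                stringsAsFactors = FALSE),
    correlations = as.data.frame(cor_df))
  jsonlite::write_json(payload, files[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}

#' Scatter plots of age against the ALPS index
#'
#' One panel per group and hemisphere with the least-squares line and the
#' sample R-squared, mirroring the study's correlation figure.
#'
#' @param records Data frame with `group`, `age_months`, `alps_left`,
#'   `alps_right`.
#' @param file Optional output path (`.svg` or `.png` by extension); when
#'   `NULL`, plots on the active device.
#' @return The correlation table from [age_correlations()], invisibly.
#' @export
plot_age_alps <- function(records, file = NULL) {
  cors <- age_correlations(records)
  scatter <- attr(cors, "scatter")
  if (is.null(scatter) || !nrow(cors)) {
    warning("nothing to plot")
    return(invisible(cors))
  }
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 8, height = 8),
           png = grDevices::png(file, width = 1200, height = 1200,
                                res = 150),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off())
  }
  graphics::par(mfrow = c(nrow(cors) %/% 2 + nrow(cors) %% 2, 2),
                mar = c(4, 4, 2.5, 1))
  for (i in seq_len(nrow(cors))) {
    g <- cors$group[i]; h <- cors$hemisphere[i]
    d <- scatter[scatter$group == g & scatter$hemisphere == h, ]
    graphics::plot(d$age_months, d$alps, pch = 19, col = "grey30",
                   xlab = "Age (months)", ylab = "ALPS index",
                   main = sprintf("%s, %s (R² = %.3f)", g, h,
                                  cors$r_squared[i]))
    graphics::abline(stats::lm(alps ~ age_months, data = d), col = "red3",
                     lwd = 2)
  }
  invisible(cors)
}
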