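test_that("Mann-Whitney U matches full enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)               # 2 / choose(6, 3)
  expect_equal(res$p, enum_mw_p(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$method, "exact")
  # random tie-free samples agree with the enumeration oracle
  set.seed(9)
  for (k in 1:8) {
    x <- sample(seq(0, 1, by = 1e-4), 5)
    y <- sample(seq(2, 3, by = 1e-4), 4)
    y[1] <- x[1] + 0.33  # interleave
    expect_equal(mann_whitney_u(x, y)$p, enum_mw_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("identical samples give p = 1 and extremes behave", {
  res <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p, 1)
  expect_equal(res$U, 4.5)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # mode flag forces the route
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6),
                              mode = "approx")$method,
               "normal approximation")
  expect_warning(mann_whitney_u(c(1, 1, 2), c(2, 3, 3), mode = "exact"),
                 "ties")
})

test_that("normal approximation tracks the exact test for n1, n2 <= 6", {
  set.seed(21)
  for (n1 in 3:6) for (n2 in 3:6) {
    for (rep in 1:3) {
      x <- rnorm(n1)
      y <- rnorm(n2, mean = runif(1, -1.5, 1.5))
      pe <- mann_whitney_u(x, y, mode = "exact")$p
      pa <- mann_whitney_u(x, y, mode = "approx")$p
      expect_lt(abs(pe - pa), 0.03)
    }
  }
})

test_that("Mann-Whitney holds its type-I error at n = 30 vs 25", {
  set.seed(33)
  p <- replicate(2000, mann_whitney_u(rnorm(30), rnorm(25))$p)
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("the printed ALPS group effect is strongly detected", {
  # cohorts at the study's left-index parameters; the typical replicate
  # rejects far below the reported significance bound
  set.seed(57)
  p <- replicate(300, {
    mann_whitney_u(rnorm(30, 1.02, 0.12), rnorm(25, 1.27, 0.25))$p
  })
  expect_lt(median(p), 0.001)
  expect_gte(mean(p < 0.017), 0.9)
})

test_that("Pearson correlation matches hand-computed cases", {
  r1 <- pearson_correlation(c(0, 1, 2), c(1, 3, 5))  # y = 2x + 1
  expect_equal(r1$r, 1)
  expect_equal(r1$r_squared, 1)
  # symmetric residuals: r = 0
  r0 <- pearson_correlation(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r0$r, 0, tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
})

test_that("R^2 equals r^2 and r is invariant under affine maps", {
  set.seed(14)
  for (k in 1:10) {
    x <- rnorm(20)
    y <- 0.6 * x + rnorm(20)
    ct <- pearson_correlation(x, y)
    expect_equal(ct$r_squared, ct$r^2, tolerance = 1e-12)
    ct2 <- pearson_correlation(3.2 * x + 7, 0.5 * y - 2)
    expect_equal(ct2$r, ct$r, tolerance = 1e-12)
  }
})

test_that("mean sample R^2 follows the small-sample expectation", {
  # Delta-method expectation for bivariate-normal samples:
  # E[r^2] = Var(r) + E[r]^2 ~ rho^2 + (1 - rho^2)(1 - 2 rho^2)/n,
  # which reduces to the familiar null bias 1/n at rho = 0.
  rho <- 0.68
  n <- 30
  set.seed(70)
  r2 <- replicate(400, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    pearson_correlation(x, y)$r_squared
  })
  expected <- rho^2 + (1 - rho^2) * (1 - 2 * rho^2) / n
  expect_lt(abs(mean(r2) - expected), 0.01)
  # at rho = 0 the bias is 1/n
  set.seed(71)
  r2_null <- replicate(400, {
    pearson_correlation(rnorm(n), rnorm(n))$r_squared
  })
  expect_lt(abs(mean(r2_null) - 1 / n), 0.01)
})

test_that("group comparison applies the Bonferroni family threshold", {
  cfg <- default_cohort_config()
  coh <- sample_cohort(cfg, seed = 19)
  rec <- coh$subjects
  rec$alps_left <- rec$alps_true_left
  rec$alps_right <- rec$alps_true_right
  out <- compare_groups(rec)
  expect_s3_class(out, "alps_group_comparison")
  expect_setequal(out$variable,
                  c("alps_left", "alps_right", "age_months", "ga_weeks",
                    "sex"))
  expect_equal(unique(out$threshold), 0.05 / 3, tolerance = 1e-12)
  expect_identical(out$significant, out$p < out$threshold)
  # the ALPS effect is detected; the matched demographics are not
  expect_true(all(out$significant[out$variable %in%
                                    c("alps_left", "alps_right")]))
  expect_false(any(out$significant[out$variable %in%
                                     c("age_months", "ga_weeks", "sex")]))
  # identical groups: nothing significant
  rec2 <- rec
  rec2$group <- rep(c("A", "B"), length.out = nrow(rec2))
  set.seed(1)
  rec2$alps_left <- rnorm(nrow(rec2))
  rec2$alps_right <- rec2$alps_left
  out2 <- compare_groups(rec2)
  alps_rows <- out2$variable %in% c("alps_left", "alps_right")
  expect_false(any(out2$significant[alps_rows]))
  expect_error(compare_groups(rec[rec$group == "ASD", ]), "two groups")
  # configurable family changes the threshold
  out3 <- compare_groups(rec, family = c("alps_left", "alps_right"))
  expect_equal(unique(out3$threshold), 0.025)
  # sex can alternatively be ranked as a binary coding
  out4 <- compare_groups(rec, sex_test = "mann_whitney")
  expect_false(is.na(out4$U[out4$variable == "sex"]))
})

test_that("age correlations are computed per group and hemisphere", {
  coh <- sample_cohort(default_cohort_config(), seed = 23)
  rec <- coh$subjects
  rec$alps_left <- rec$alps_true_left
  rec$alps_right <- rec$alps_true_right
  cors <- age_correlations(rec)
  expect_equal(nrow(cors), 4L)
  expect_setequal(paste(cors$group, cors$hemisphere),
                  c("ASD left", "ASD right", "control left",
                    "control right"))
  expect_equal(cors$r_squared, cors$r^2, tolerance = 1e-12)
  expect_true(all(cors$r > 0))  # generated with positive rho
  scatter <- attr(cors, "scatter")
  expect_equal(nrow(scatter), 2L * nrow(rec))
  # degenerate stratum is skipped with a warning
  rec_deg <- rec
  rec_deg$age_months[rec_deg$group == "ASD"] <- 36
  w <- capture_warnings(cors2 <- age_correlations(rec_deg))
  expect_length(w, 2L)  # one per skipped ASD hemisphere
  expect_match(w, "zero variance", all = TRUE)
  expect_equal(nrow(cors2), 2L)
  # all-equal ages make the correlation itself undefined
  expect_error(pearson_correlation(rep(36, 10), rnorm(10)),
               "zero variance")
})

test_that("p-values render in the tables' style", {
  expect_equal(format_p(c(0.0003, 0.52, 0.0005, 0.0172)),
               c("<.001", ".520", ".001", ".017"))
  expect_equal(format_p(1), "1.000")
})

test_that("report_stats writes diffable tables and valid JSON", {
  coh <- sample_cohort(default_cohort_config(), seed = 29)
  rec <- coh$subjects
  rec$alps_left <- rec$alps_true_left
  rec$alps_right <- rec$alps_true_right
  comp <- compare_groups(rec)
  cors <- age_correlations(rec)
  dir <- file.path(tempdir(), "alps-report-test")
  files <- report_stats(comp, cors, dir)
  expect_true(all(file.exists(files)))
  alps_tab <- utils::read.csv(files[["alps"]], check.names = FALSE)
  expect_equal(names(alps_tab), c("variable", "ASD", "control", "P value"))
  expect_match(alps_tab[["ASD"]][1], "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
  expect_match(alps_tab[["P value"]], "^(<\\.001|\\.\\d{3}|1\\.000)$",
               all = TRUE)
  js <- jsonlite::read_json(files[["json"]])
  expect_named(js, c("groups", "comparisons", "correlations"))
  expect_length(js$correlations, 4L)
  # empty input still yields files and valid JSON
  empty <- compare_groups(data.frame(group = rep(c("A", "B"), 3),
                                     v = rnorm(6)),
                          variables = "v", family = "v")
  files2 <- report_stats(empty[0, ], NULL,
                         file.path(tempdir(), "alps-report-empty"))
  expect_true(all(file.exists(files2)))
  expect_silent(jsonlite::read_json(files2[["json"]]))
})
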