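test_that("Shapiro-Wilk wrapper separates normal from contaminated samples", {
  s <- shapiro_wilk(c(2.1, 2.3, 1.9, 2.2, 2.0, 2.4, 2.1, 2.2))
  expect_gt(s$p, 0.05)
  set.seed(11)
  contaminated <- c(rnorm(20), 100)
  expect_lt(shapiro_wilk(contaminated)$p, 0.05)
  expect_error(shapiro_wilk(c(1, 2)), class = "spherosed_validation_error")
})

test_that("Tukey fences follow the linear-interpolation quartile convention", {
  tk <- tukey_outliers(c(1, 2, 3, 4, 100))
  # hand-computed under type-7 quartiles: Q1 = 2, Q3 = 4, upper fence = 7
  expect_identical(tk$removed, 100)
  expect_identical(tk$kept, c(1, 2, 3, 4))
  # all-equal values: IQR = 0, nothing removed
  expect_length(tukey_outliers(rep(3.3, 6))$removed, 0)
  # idempotence
  again <- tukey_outliers(tk$kept)
  expect_length(again$removed, 0)
  expect_error(tukey_outliers(c(1, 2, 3)),
               class = "spherosed_validation_error")
})

test_that("Tukey fences agree with the brute-force quartile formula", {
  set.seed(21)
  for (i in 1:30) {
    x <- round(rnorm(sample(4:12, 1), 10, 4), 1)
    fences <- bf_tukey_fences(x)
    tk <- tukey_outliers(x)
    expect_setequal(tk$removed, x[x < fences[1] | x > fences[2]])
  }
})

test_that("the cleaning pipeline removes exactly the injected outliers", {
  set.seed(5)
  base <- rnorm(30, 1.05, 0.01)
  clean <- normality_pipeline(base)
  expect_identical(clean$report$n_removed, 0L)
  expect_true(clean$report$converged)
  expect_identical(clean$cleaned, base)
  dirty <- c(base, 2.0, 0.1)
  res <- normality_pipeline(dirty)
  expect_setequal(res$report$removed_values, c(2.0, 0.1))
  expect_true(res$report$converged)
  expect_setequal(res$cleaned, base)
})

test_that("a sample that stays non-normal reports non-convergence, no error", {
  # strongly bimodal: non-normal, but with no points beyond the Tukey
  # fences, so one cleaning round cannot fix it
  set.seed(13)
  x <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  res <- normality_pipeline(x)
  expect_false(res$report$converged)
  expect_lt(res$report$sw_p_after, 0.05)
  expect_identical(res$report$n_removed, 0L)
})

test_that("the pipeline never alters a sample already normal at alpha", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(25, 5, 1)
    if (shapiro_wilk(x)$p >= 0.05) {
      expect_identical(normality_pipeline(x)$cleaned, x)
    }
  }
})

test_that("Student t-test matches the pooled-variance formula", {
  cg <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  oracle <- bf_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cg$t, oracle$t, tolerance = 1e-12)   # -1.224745
  expect_equal(cg$df, 4)
  expect_equal(cg$p, oracle$p, tolerance = 1e-12)
  # identical samples
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)),
               class = "spherosed_validation_error")
  # degenerate variances
  expect_equal(compare_groups(rep(2, 4), rep(2, 5))$p, 1)
  expect_error(compare_groups(rep(2, 4), rep(3, 5)),
               class = "spherosed_degenerate_variance")
})

test_that("dose-response correlation matches the covariance formula", {
  conc <- c(0, 250, 500)
  expect_equal(pearson_dose_response(conc, c(1, 2, 3)), 1)
  expect_equal(pearson_dose_response(conc, c(3, 2, 1)), -1)
  means <- c(1.0, 1.1, 1.05)
  expect_equal(pearson_dose_response(conc, means), bf_pearson(conc, means),
               tolerance = 1e-12)
  expect_error(pearson_dose_response(conc, rep(2, 3)),
               class = "spherosed_constant_input")
})

test_that("one-way ANOVA matches brute-force sums of squares", {
  oa <- oneway_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(oa$F, 1.5, tolerance = 1e-12)
  expect_equal(oa$df_between, 1)
  expect_equal(oa$df_within, 4)
  oracle <- bf_anova(c(1, 2, 3, 2, 3, 4), rep(c("a", "b"), each = 3))
  expect_equal(oa$p, oracle$p, tolerance = 1e-12)
})

test_that("fixation ANOVA gives F = 0 when live and fixed cells coincide", {
  rows <- expand.grid(condition = c("CTRL", "CZB250", "CZB500"),
                      state = c("live", "fixed"),
                      parameter = c("density", "weight", "diameter"),
                      rep = 1:4, stringsAsFactors = FALSE)
  base <- c(density = 1.05, weight = 4.4, diameter = 200)
  shift <- c(CTRL = 0, CZB250 = 0.02, CZB500 = 0.04)
  # identical in both states; within-cell replicate offsets identical too
  rows$value <- base[rows$parameter] * (1 + shift[rows$condition]) +
    rows$rep * 1e-3
  rows$spheroid_id <- sprintf("s%03d", seq_len(nrow(rows)))
  tab <- suppressWarnings(cohort_table(rows))
  fa <- fixation_anova(tab)
  expect_lt(fa$F, 1e-20)
  # single state only is an error
  expect_error(fixation_anova(tab[tab$state == "live", ]),
               class = "spherosed_validation_error")
})

test_that("standard-curve calibration inverts an exact line", {
  conc <- c(0, 1, 2, 3)
  curve <- calibrate_standard_curve(conc, 2 * conc + 1)
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 1, tolerance = 1e-12)
  expect_equal(curve$r2, 1)
  expect_equal(apply_curve(curve, 7), 3, tolerance = 1e-12)
  expect_error(calibrate_standard_curve(rep(2, 4), c(1, 2, 3, 4)),
               class = "spherosed_calibration_error")
})

test_that("noisy calibration matches the closed-form normal equations", {
  tab <- gen_standard_curve(slope = 3.2, intercept = 0.7, noise_sd = 0.3,
                            n = 10, seed = 9)
  curve <- calibrate_standard_curve(tab$concentration, tab$fluorescence)
  oracle <- bf_ols(tab$concentration, tab$fluorescence)
  expect_equal(curve$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(curve$intercept, oracle$intercept, tolerance = 1e-10)
})

test_that("cohort summary detects a known density shift at both doses", {
  sc <- cohort_scenario(
    means = list(CTRL = c(density = 1.048, weight = 4.4, diameter = 200),
                 CZB250 = c(density = 1.058, weight = 4.4, diameter = 200),
                 CZB500 = c(density = 1.058, weight = 4.4, diameter = 200)),
    sds = c(density = 0.004, weight = 0.45, diameter = 12),
    n_per_cell = 15)
  g <- gen_cohort(sc, seed = 31)
  s <- cohort_summary(g$table)
  dens <- s$comparisons[s$comparisons$parameter == "density", ]
  expect_true(all(dens$p < 0.01))
  expect_true(all(dens$t > 0))  # treated denser than control
})

test_that("cohort summary reproduces the simulated direction of effect", {
  g <- gen_cohort(cohort_scenario(), seed = 17)
  s <- cohort_summary(g$table)
  r <- s$correlations
  expect_true(all(r$r[r$parameter == "density"] > 0))
  expect_true(all(r$r[r$parameter == "weight"] < 0))
  expect_true(all(r$r[r$parameter == "diameter"] < 0))
})

test_that("cohort tables validate their enumerations", {
  df <- data.frame(spheroid_id = "a", condition = "CZB999", state = "live",
                   parameter = "density", value = 1.05)
  expect_error(cohort_table(df), class = "spherosed_schema_error")
  df$condition <- "CTRL"; df$state <- "thawed"
  expect_error(cohort_table(df), class = "spherosed_schema_error")
  df$state <- "live"; df$parameter <- "mass"
  expect_error(cohort_table(df), class = "spherosed_schema_error")
  df$parameter <- "density"
  expect_warning(cohort_table(df), "fewer than 10")
})
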