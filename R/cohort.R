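COHORT_CONDITIONS <- c("CTRL", "CZB250", "CZB500")
COHORT_STATES <- c("live", "fixed")
COHORT_PARAMETERS <- c("density", "weight", "diameter")
CONDITION_CONC <- c(CTRL = 0, CZB250 = 250, CZB500 = 500)  # nM

#' Validate a long-format cohort table
#'
#' Rows are per-spheroid measurements keyed by treatment condition
#' (`CTRL`, `CZB250`, `CZB500`), sample state (`live`, `fixed`) and
#' parameter (`density` in g/cm^3, `weight` in ug, `diameter` in um).
#' Cells (condition x state x parameter) with fewer than 10 spheroids
#' trigger a warning, matching the convention of analyzing at least 10
#' spheroids per condition.
#'
#' @param df data.frame with columns `spheroid_id`, `condition`, `state`,
#'   `parameter`, `value`.
#' @param min_n warn below this per-cell count (default 10).
#' @return the validated data.frame, classed `cohort_table`.
#' @export
cohort_table <- function(df, min_n = 10) {
  need <- c("spheroid_id", "condition", "state", "parameter", "value")
  ss_check(is.data.frame(df) && all(need %in% names(df)),
           paste("cohort table must have columns:", paste(need, collapse = ", ")))
  bad <- which(!df$condition %in% COHORT_CONDITIONS)
  if (length(bad)) ss_stop(sprintf(
    "row %d: unknown condition '%s'", bad[1], df$condition[bad[1]]),
    "spherosed_schema_error")
  bad <- which(!df$state %in% COHORT_STATES)
  if (length(bad)) ss_stop(sprintf(
    "row %d: unknown state '%s'", bad[1], df$state[bad[1]]),
    "spherosed_schema_error")
  bad <- which(!df$parameter %in% COHORT_PARAMETERS)
  if (length(bad)) ss_stop(sprintf(
    "row %d: unknown parameter '%s'", bad[1], df$parameter[bad[1]]),
    "spherosed_schema_error")
  ss_check(all(is.finite(df$value)), "cohort values must be finite")
  cnt <- stats::aggregate(value ~ condition + state + parameter, df, length)
  if (any(cnt$value < min_n))
    warning(sprintf("%d cohort cell(s) have fewer than %d spheroids",
                    sum(cnt$value < min_n), min_n), call. = FALSE)
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list `W`, `p`.
#' @export
shapiro_wilk <- function(values) {
  ss_check(is.numeric(values) && all(is.finite(values)),
           "values must be finite")
  n <- length(values)
  ss_check(n >= 3 && n <= 5000, "Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) return(list(W = 1, p = 1))  # degenerate: treat as normal
  t <- stats::shapiro.test(values)
  list(W = unname(t$statistic), p = t$p.value)
}

#' Tukey-fence outlier identification
#'
#' Quartiles by linear interpolation (R's default type-7 convention);
#' fences at `Q1 - k IQR` and `Q3 + k IQR`; values strictly outside the
#' fences are outliers. With `IQR = 0` nothing is removed.
#'
#' @param values numeric vector, n >= 4.
#' @param k whisker coefficient (default 1.5).
#' @return list `kept`, `removed`.
#' @examples
#' tukey_outliers(c(1, 2, 3, 4, 100))  # removes 100
#' @export
tukey_outliers <- function(values, k = 1.5) {
  ss_check(is.numeric(values) && all(is.finite(values)),
           "values must be finite")
  ss_check(length(values) >= 4, "Tukey fences require n >= 4")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- values < lo | values > hi
  list(kept = values[!out], removed = values[out])
}

#' Normality-gated outlier-elimination pipeline
#'
#' Shapiro-Wilk first; if the sample is non-normal at `alpha`, one round
#' (by default) of Tukey-fence removal, then Shapiro-Wilk again to confirm.
#' Normal inputs pass through untouched.
#'
#' @param values numeric vector, n >= 4.
#' @param alpha normality significance level (default 0.05).
#' @param k Tukey whisker coefficient (default 1.5).
#' @param max_iter maximum removal rounds (default 1).
#' @return list `cleaned` and `report` (fields `n_initial`, `n_removed`,
#'   `removed_values`, `sw_p_before`, `sw_p_after`, `converged`).
#' @export
normality_pipeline <- function(values, alpha = 0.05, k = 1.5, max_iter = 1) {
  ss_check(length(values) >= 4, "pipeline requires n >= 4")
  sw0 <- shapiro_wilk(values)
  cleaned <- values
  removed <- numeric()
  p <- sw0$p
  iter <- 0
  while (p < alpha && iter < max_iter) {
    iter <- iter + 1
    tk <- tukey_outliers(cleaned, k)
    if (length(tk$removed) == 0) break
    if (length(tk$kept) < 3)
      ss_stop("outlier removal would leave fewer than 3 values",
              "spherosed_pipeline_error")
    removed <- c(removed, tk$removed)
    cleaned <- tk$kept
    p <- shapiro_wilk(cleaned)$p
  }
  list(cleaned = cleaned,
       report = list(n_initial = length(values), n_removed = length(removed),
                     removed_values = removed, sw_p_before = sw0$p,
                     sw_p_after = p, converged = p >= alpha))
}

#' Two-tailed unpaired Student t-test between two groups
#'
#' Equal-variance (pooled) t-test with `df = n_a + n_b - 2`; groups are
#' summarized as mean and SD. When both groups have zero variance, equal
#' means give `t = 0, p = 1` by convention and unequal means are an error.
#'
#' @param a,b numeric vectors, each n >= 3.
#' @return list `t`, `df`, `p`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_groups <- function(a, b) {
  ss_check(length(a) >= 3 && length(b) >= 3, "each group needs n >= 3")
  check_finite(a, "a"); check_finite(b, "b")
  ma <- mean(a); mb <- mean(b); sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 && sb == 0) {
    if (ma == mb)
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = ma, sd_a = sa, mean_b = mb, sd_b = sb))
    ss_stop("zero pooled variance with unequal means",
            "spherosed_degenerate_variance")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = ma, sd_a = sa, mean_b = mb, sd_b = sb)
}

#' Pearson dose-response correlation of per-concentration means
#'
#' @param concentrations drug concentrations (one per group mean).
#' @param group_means per-concentration mean values.
#' @return Pearson r in `[-1, 1]`.
#' @export
pearson_dose_response <- function(concentrations, group_means) {
  ss_check(length(concentrations) == length(group_means),
           "inputs must be paired")
  ss_check(length(concentrations) >= 3, "need at least 3 paired points")
  check_finite(concentrations, "concentrations")
  check_finite(group_means, "group_means")
  if (stats::sd(concentrations) == 0 || stats::sd(group_means) == 0)
    ss_stop("constant input: correlation undefined",
            "spherosed_constant_input")
  stats::cor(concentrations, group_means, method = "pearson")
}

#' Classical one-way ANOVA of numeric values by group
#'
#' @param values numeric vector. @param groups factor-like grouping.
#' @return list `F`, `df_between`, `df_within`, `p`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  ss_check(nlevels(groups) >= 2, "need at least 2 groups")
  ss_check(all(table(groups) >= 2), "each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], df_between = as.integer(tab[["Df"]][1]),
       df_within = as.integer(tab[["Df"]][2]), p = tab[["Pr(>F)"]][1])
}

#' One-way ANOVA of the total fixation effect
#'
#' Estimates the overall effect of fixation on the sedimentation readouts:
#' per-(condition x state x parameter) cell means are computed, each
#' parameter is z-scored across its cells (so density in g/cm^3, weight in
#' ug and diameter in um become commensurable), and a one-way ANOVA with
#' state (live vs fixed) as the single factor is applied to the
#' standardized cell means.
#'
#' @param table a [cohort_table()].
#' @return list `F`, `df_between`, `df_within`, `p`.
#' @export
fixation_anova <- function(table) {
  ss_check(all(COHORT_STATES %in% unique(table$state)),
           "both live and fixed states must be present")
  cm <- stats::aggregate(value ~ condition + state + parameter, table, mean)
  for (p in unique(cm$parameter)) {
    i <- cm$parameter == p
    ss_check(stats::sd(cm$value[i]) > 0 || sum(i) < 2,
             "cannot standardize a constant parameter")
    cm$value[i] <- (cm$value[i] - mean(cm$value[i])) /
      max(stats::sd(cm$value[i]), .Machine$double.eps)
  }
  ss_check(all(table(cm$state) >= 2), "each state needs at least 2 cell means")
  oneway_anova(cm$value, cm$state)
}

#' Fluorescence standard-curve calibration
#'
#' Ordinary least squares of fluorescence on concentration;
#' [apply_curve()] inverts the line to map a fluorescence reading to a
#' concentration.
#'
#' @param std_conc standard concentrations (>= 3, not all equal).
#' @param std_fluorescence matching fluorescence readings.
#' @return object of class `standard_curve`: `slope`, `intercept`, `r2`.
#' @export
calibrate_standard_curve <- function(std_conc, std_fluorescence) {
  ss_check(length(std_conc) == length(std_fluorescence), "inputs must be paired")
  ss_check(length(std_conc) >= 3, "need at least 3 standards")
  check_finite(std_conc, "std_conc"); check_finite(std_fluorescence, "std_fluorescence")
  if (length(unique(std_conc)) < 2)
    ss_stop("standards need at least two distinct concentrations",
            "spherosed_calibration_error")
  fit <- stats::lm(std_fluorescence ~ std_conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0)
    ss_stop("flat standard curve (slope 0)", "spherosed_calibration_error")
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact standards fit cleanly
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 r2 = r2), class = "standard_curve")
}

#' @rdname calibrate_standard_curve
#' @param curve a `standard_curve`.
#' @param fluorescence reading(s) to convert.
#' @export
apply_curve <- function(curve, fluorescence) {
  ss_check(inherits(curve, "standard_curve"), "`curve` must be a standard_curve")
  (fluorescence - curve$intercept) / curve$slope
}

#' Full cohort statistical report
#'
#' Per (condition x state x parameter) cell: the normality-gated cleaning
#' pipeline, then per (state x parameter) Student t-tests of each
#' treatment against CTRL on the cleaned values, and the Pearson
#' dose-response correlation of the cleaned cell means against the drug
#' concentrations (0, 250, 500 nM).
#'
#' @param table a [cohort_table()] (or plain data.frame with its columns).
#' @param alpha normality gate (default 0.05).
#' @param k Tukey whisker coefficient (default 1.5).
#' @return list of data.frames: `cells` (n, mean, sd, cleaning report
#'   fields), `comparisons` (t, df, p vs CTRL), `correlations`
#'   (dose-response r), `cleaned` (box-plot-ready long table).
#' @export
cohort_summary <- function(table, alpha = 0.05, k = 1.5) {
  if (!inherits(table, "cohort_table"))
    table <- suppressWarnings(cohort_table(table))
  cells <- NULL
  cleaned_rows <- NULL
  store <- list()
  for (st in intersect(COHORT_STATES, unique(table$state))) {
    for (par in intersect(COHORT_PARAMETERS, unique(table$parameter))) {
      for (cond in intersect(COHORT_CONDITIONS, unique(table$condition))) {
        v <- table$value[table$condition == cond & table$state == st &
                           table$parameter == par]
        if (length(v) == 0) next
        np <- normality_pipeline(v, alpha = alpha, k = k)
        key <- paste(cond, st, par, sep = ".")
        store[[key]] <- np$cleaned
        cells <- rbind(cells, data.frame(
          condition = cond, state = st, parameter = par,
          n = length(np$cleaned), mean = mean(np$cleaned),
          sd = stats::sd(np$cleaned), n_removed = np$report$n_removed,
          sw_p_before = np$report$sw_p_before,
          sw_p_after = np$report$sw_p_after,
          converged = np$report$converged))
        cleaned_rows <- rbind(cleaned_rows, data.frame(
          condition = cond, state = st, parameter = par, value = np$cleaned))
      }
    }
  }
  comparisons <- NULL
  correlations <- NULL
  for (st in unique(cells$state)) {
    for (par in unique(cells$parameter)) {
      ctrl <- store[[paste("CTRL", st, par, sep = ".")]]
      for (cond in c("CZB250", "CZB500")) {
        trt <- store[[paste(cond, st, par, sep = ".")]]
        if (is.null(ctrl) || is.null(trt)) next
        cg <- compare_groups(trt, ctrl)
        comparisons <- rbind(comparisons, data.frame(
          state = st, parameter = par, comparison = paste0(cond, "_vs_CTRL"),
          t = cg$t, df = cg$df, p = cg$p,
          mean_treated = cg$mean_a, sd_treated = cg$sd_a,
          mean_ctrl = cg$mean_b, sd_ctrl = cg$sd_b))
      }
      means <- vapply(COHORT_CONDITIONS, function(cond) {
        v <- store[[paste(cond, st, par, sep = ".")]]
        if (is.null(v)) NA_real_ else mean(v)
      }, numeric(1))
      if (!anyNA(means)) {
        correlations <- rbind(correlations, data.frame(
          state = st, parameter = par,
          r = pearson_dose_response(unname(CONDITION_CONC), unname(means))))
      }
    }
  }
  list(cells = cells, comparisons = comparisons, correlations = correlations,
       cleaned = cleaned_rows)
}
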