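# Brute-force statistical oracles, kept deliberately independent of the
# package implementation (sums and closed-form formulas only).

bf_mean <- function(x) sum(x) / length(x)

bf_ss <- function(x) {
  m <- bf_mean(x)
  sum((x - m)^2)
}

# pooled-variance two-sample t-test
bf_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (bf_ss(a) + bf_ss(b)) / (na + nb - 2)
  t <- (bf_mean(a) - bf_mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# one-way ANOVA from raw sums of squares
bf_anova <- function(values, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  grand <- bf_mean(values)
  ssb <- sum(vapply(gl, function(g) {
    v <- values[groups == g]
    length(v) * (bf_mean(v) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(gl, function(g) bf_ss(values[groups == g]), numeric(1)))
  df1 <- length(gl) - 1
  df2 <- length(values) - length(gl)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df_between = df1, df_within = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

bf_pearson <- function(x, y) {
  sxy <- sum((x - bf_mean(x)) * (y - bf_mean(y)))
  sxy / sqrt(bf_ss(x) * bf_ss(y))
}

# type-7 (linear interpolation) quartile, written out from the definition
bf_quartile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}

bf_tukey_fences <- function(x, k = 1.5) {
  q1 <- bf_quartile(x, 0.25)
  q3 <- bf_quartile(x, 0.75)
  c(q1 - k * (q3 - q1), q3 + k * (q3 - q1))
}

# closed-form simple OLS by the normal equations
bf_ols <- function(x, y) {
  sxx <- bf_ss(x)
  sxy <- sum((x - bf_mean(x)) * (y - bf_mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = bf_mean(y) - slope * bf_mean(x))
}

# shared small fixtures
water_like <- function() fluid_medium(1000, viscosity = 1e-3)
default_chan <- function() channel_geometry()

make_track <- function(x, y, radius, valid = rep(TRUE, length(y))) {
  structure(list(x = x, y = y, radius = radius, valid = valid,
                 interpolated = rep(FALSE, length(y))),
            class = "spheroid_track")
}
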