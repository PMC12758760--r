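# Histology and sperm-measurement statistics: pixel proportions from label
# masks, pooled one-tailed t-tests that accept raw values or printed
# summaries, Cohen's d / U3, and hemacytometer sperm concentration.

#' Group summary (n, mean, standard error)
#'
#' Container for printed summary statistics; the standard deviation is
#' reconstructed as `se * sqrt(n)` where needed.
#'
#' @param n Sample size (>= 2 for variance-based tests).
#' @param mean Group mean.
#' @param se Standard error of the mean (>= 0).
#' @return A list of class `"group_summary"`.
#' @export
group_summary <- function(n, mean, se) {
  stopifnot(n >= 1, se >= 0)
  structure(list(n = as.integer(n), mean = mean, se = se),
            class = "group_summary")
}

summarize_group <- function(g) {
  if (inherits(g, "group_summary")) {
    list(n = g$n, mean = g$mean, sd = g$se * sqrt(g$n))
  } else if (is.numeric(g)) {
    if (length(g) < 2) stop("raw groups need n >= 2")
    list(n = length(g), mean = mean(g), sd = stats::sd(g))
  } else stop("group must be a numeric vector or a group_summary")
}

#' Proportion of sperm pixels in a labeled histology image
#'
#' Labels: 0 = background, 1 = testis tissue other than sperm, 2 = sperm.
#' Returns sperm pixels divided by all tissue pixels (labels 1 and 2);
#' background never enters the denominator.
#'
#' @param mask Integer matrix with values in `{0, 1, 2}`.
#' @return Fraction in `[0, 1]`.
#' @export
pixel_proportion <- function(mask) {
  if (!is.matrix(mask) && !is.array(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0L, 1L, 2L))) stop("mask labels must be 0, 1 or 2")
  tissue <- sum(mask == 1L) + sum(mask == 2L)
  if (tissue == 0) stop("no tissue pixels in mask")
  sum(mask == 2L) / tissue
}

#' One-tailed two-sample t-test assuming equal variance
#'
#' Pooled-variance t statistic with `df = n1 + n2 - 2`; groups may be raw
#' numeric vectors or [group_summary()] objects (printed n/mean/SE), and the
#' two input forms give identical results when the summaries match the raw
#' data. With zero pooled variance and equal means the p-value is 0.5 by
#' convention, flagged in the output.
#'
#' @param group1,group2 Numeric vectors or [group_summary()] objects.
#' @param alternative `"group1_less"` (mean1 < mean2) or `"group1_greater"`.
#' @return A list with `t`, `df`, `p`, and `degenerate` flag.
#' @export
one_tailed_t_equal_var <- function(group1, group2,
                                   alternative = c("group1_less",
                                                   "group1_greater")) {
  alternative <- match.arg(alternative)
  g1 <- summarize_group(group1)
  g2 <- summarize_group(group2)
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2")
  df <- g1$n + g2$n - 2
  pooled_var <- ((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / df
  degenerate <- FALSE
  if (pooled_var == 0) {
    if (g1$mean == g2$mean) {
      return(list(t = 0, df = df, p = 0.5, degenerate = TRUE))
    }
    t_stat <- sign(g1$mean - g2$mean) * Inf
  } else {
    t_stat <- (g1$mean - g2$mean) /
      sqrt(pooled_var * (1 / g1$n + 1 / g2$n))
  }
  p <- if (alternative == "group1_less") {
    stats::pt(t_stat, df)
  } else {
    stats::pt(t_stat, df, lower.tail = FALSE)
  }
  list(t = t_stat, df = df, p = p, degenerate = degenerate)
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean2 - mean1) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`. Positive `d`
#' means group 2 has the larger mean.
#'
#' @param group1,group2 Numeric vectors or [group_summary()] objects.
#' @return The standardized mean difference.
#' @export
cohens_d <- function(group1, group2) {
  g1 <- summarize_group(group1)
  g2 <- summarize_group(group2)
  if (g1$n < 2 || g2$n < 2) stop("both groups need n >= 2")
  pooled_sd <- sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) /
                      (g1$n + g2$n - 2))
  if (pooled_sd == 0) stop("zero pooled standard deviation")
  (g2$mean - g1$mean) / pooled_sd
}

#' Cohen's U3
#'
#' Percentage of one group's distribution lying below the other group's
#' mean under normal theory: `100 * pnorm(d)`.
#'
#' @param d Cohen's d.
#' @return Percentage in `(0, 100)`.
#' @export
cohens_u3 <- function(d) {
  stopifnot(is.finite(d))
  100 * stats::pnorm(d)
}

#' Hemacytometer sperm concentration per mg of testis
#'
#' Chamber concentration `chamber_count / chamber_volume * dilution_factor`
#' (cells/mL), scaled to the whole suspension and divided by testis mass.
#'
#' @param chamber_count Cells counted in the chamber.
#' @param chamber_volume_mL Chamber volume in mL.
#' @param dilution_factor Fold dilution of the counted aliquot.
#' @param suspension_volume_mL Total suspension volume in mL.
#' @param testis_mass_mg Testis mass in mg.
#' @return A list with `concentration_per_mL` and `sperm_per_mg`.
#' @export
sperm_concentration <- function(chamber_count, chamber_volume_mL,
                                dilution_factor, suspension_volume_mL,
                                testis_mass_mg) {
  if (chamber_volume_mL <= 0 || suspension_volume_mL <= 0 ||
      testis_mass_mg <= 0 || dilution_factor <= 0)
    stop("volumes, mass and dilution must be positive")
  conc <- chamber_count / chamber_volume_mL * dilution_factor
  list(concentration_per_mL = conc,
       sperm_per_mg = conc * suspension_volume_mL / testis_mass_mg)
}
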