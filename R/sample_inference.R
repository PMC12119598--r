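#' Two-group sample with covariate and outcome
#'
#' Bundles raw observations for two groups of equal size n: covariate and
#' outcome values per unit. n >= 3 is required so that the ANCOVA error df
#' (2n - 3) and the comparator df (2(n - 1)) are both positive and variance
#' estimates are nondegenerate.
#'
#' @param x1,y1 Covariate and outcome values of group 1 (length n).
#' @param x2,y2 Covariate and outcome values of group 2 (same length).
#' @param labels Optional character vector of the two group labels (used by
#'   file readers/writers; defaults to "1" and "2").
#' @return An object of class `"two_group_sample"`.
#' @export
two_group_sample <- function(x1, y1, x2, y2, labels = c("1", "2")) {
  n <- length(x1)
  if (length(y1) != n || length(x2) != n || length(y2) != n)
    stop("groups must have equal size: x1, y1, x2, y2 must all have the same length",
         call. = FALSE)
  if (n < 3)
    stop("per-group size must be at least 3", call. = FALSE)
  vals <- c(x1, y1, x2, y2)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("all covariate and outcome values must be finite numbers", call. = FALSE)
  if (length(labels) != 2L || anyDuplicated(labels))
    stop("'labels' must be two distinct group labels", call. = FALSE)
  structure(list(x1 = as.numeric(x1), y1 = as.numeric(y1),
                 x2 = as.numeric(x2), y2 = as.numeric(y2),
                 n = n, labels = as.character(labels)),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat(sprintf("Two-group sample, n = %d per group (groups %s, %s)\n",
              x$n, x$labels[1], x$labels[2]))
  cat(sprintf("  group %s: mean x = %g, mean y = %g\n",
              x$labels[1], mean(x$x1), mean(x$y1)))
  cat(sprintf("  group %s: mean x = %g, mean y = %g\n",
              x$labels[2], mean(x$x2), mean(x$y2)))
  invisible(x)
}

#' Pooled within-group summary statistics
#'
#' Computes the building blocks of the two-group ANCOVA: group means, mean
#' differences (always group 1 minus group 2), pooled within-group sums of
#' squares and products (every deviation is taken from its own group mean,
#' never the grand mean), the pooled slope estimate `b = s_xy / s_xx`, the
#' pooled squared correlation `r2`, the unbiased covariate variance estimate
#' `s_x2 = s_xx / (2(n-1))`, the covariate imbalance statistic
#' `f = n(n-1) (dx)^2 / s_xx` (the F statistic comparing the covariate means,
#' equal to `(n/2) d_p^2`), and the standardized covariate mean difference
#' `d_p` (Cohen's d for the covariate).
#'
#' Sums of squares use a two-pass scheme (means first, then squared
#' deviations) for numerical stability.
#'
#' @param sample A [two_group_sample()].
#' @return An object of class `"ancova_sample_stats"`.
#' @export
sample_statistics <- function(sample) {
  if (!inherits(sample, "two_group_sample"))
    stop("'sample' must be a 'two_group_sample' object", call. = FALSE)
  n <- sample$n
  mx1 <- mean(sample$x1); mx2 <- mean(sample$x2)
  my1 <- mean(sample$y1); my2 <- mean(sample$y2)
  dx1 <- sample$x1 - mx1; dx2 <- sample$x2 - mx2
  dy1 <- sample$y1 - my1; dy2 <- sample$y2 - my2
  s_xx <- sum(dx1^2) + sum(dx2^2)
  s_yy <- sum(dy1^2) + sum(dy2^2)
  s_xy <- sum(dx1 * dy1) + sum(dx2 * dy2)
  if (s_xx == 0)
    stop("degenerate covariate: all within-group covariate values identical (s_xx = 0)",
         call. = FALSE)
  b <- s_xy / s_xx
  r2 <- if (s_yy == 0) 0 else s_xy^2 / (s_xx * s_yy)
  s_x2 <- s_xx / (2 * (n - 1))
  delta_x_bar <- mx1 - mx2
  delta_y_bar <- my1 - my2
  structure(list(
    n = n,
    mean_x1 = mx1, mean_x2 = mx2, mean_y1 = my1, mean_y2 = my2,
    delta_x_bar = delta_x_bar, delta_y_bar = delta_y_bar,
    s_xx = s_xx, s_yy = s_yy, s_xy = s_xy,
    b = b, r2 = r2, s_x2 = s_x2,
    f = n * (n - 1) * delta_x_bar^2 / s_xx,
    d_p = delta_x_bar / sqrt(s_x2)
  ), class = "ancova_sample_stats")
}

#' @export
print.ancova_sample_stats <- function(x, ...) {
  cat(sprintf("Sample statistics (n = %d per group)\n", x$n))
  cat(sprintf("  means: x %g / %g, y %g / %g\n",
              x$mean_x1, x$mean_x2, x$mean_y1, x$mean_y2))
  cat(sprintf("  dx = %g, dy = %g\n", x$delta_x_bar, x$delta_y_bar))
  cat(sprintf("  s_xx = %g, s_yy = %g, s_xy = %g\n", x$s_xx, x$s_yy, x$s_xy))
  cat(sprintf("  slope b = %.3f, r^2 = %.3f\n", x$b, x$r2))
  cat(sprintf("  covariate imbalance f = %.3f (d_p = %.3f)\n", x$f, x$d_p))
  invisible(x)
}

#' ANCOVA adjusted-mean test
#'
#' The two-group ANCOVA F test of the adjusted mean difference. With pooled
#' within-group sums `s_xx`, `s_yy`, `s_xy`, slope `b` and imbalance `f`:
#' \deqn{MST = n(n-1)\,(\Delta\bar y - b \Delta\bar x)^2 / (2(n-1) + f),}
#' \deqn{MSE = (1 - r^2)\, s_{yy} / (2n - 3),}
#' and `F = MST/MSE` with df (1, 2n-3). Equivalently `t = adjusted_diff / se`
#' with `se = sqrt(MSE * (2/n) * (1 + (n/2) (dx)^2 / s_xx))`; `F == t^2`. The
#' two-sided 1-alpha confidence interval for the adjusted difference is
#' `adjusted_diff +/- t_{2n-3}(alpha/2) * se`, and the F test rejects at level
#' alpha iff the interval excludes zero.
#'
#' If the fit is perfect (`MSE == 0`) with a nonzero adjusted difference the
#' F statistic is reported as `Inf` with p = 0; the no-signal no-noise 0/0
#' case reports F = 0, p = 1.
#'
#' @param sample A [two_group_sample()].
#' @param alpha Level in (0,1) for the confidence interval.
#' @return An object of class `"ancova_fit"` with fields `stats` (the
#'   [sample_statistics()]), `mst`, `mse`, `f_stat`, `df`, `t_stat`,
#'   `adjusted_diff`, `se`, `ci`, `p`, `alpha`.
#' @export
ancova_test <- function(sample, alpha = 0.05) {
  check_alpha(alpha)
  st <- sample_statistics(sample)
  n <- st$n
  df2 <- 2 * n - 3
  adjusted_diff <- st$delta_y_bar - st$b * st$delta_x_bar
  mst <- n * (n - 1) * adjusted_diff^2 / (2 * (n - 1) + st$f)
  mse <- (1 - st$r2) * st$s_yy / df2
  se <- sqrt(mse * (2 / n) * (1 + (n / 2) * st$delta_x_bar^2 / st$s_xx))
  if (mse > 0) {
    f_stat <- mst / mse
    t_stat <- adjusted_diff / se
    p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  } else if (mst > 0) {          # perfect fit, real signal
    f_stat <- Inf
    t_stat <- sign(adjusted_diff) * Inf
    p <- 0
  } else {                       # no signal, no noise: conservative convention
    f_stat <- 0
    t_stat <- 0
    p <- 1
  }
  half <- stats::qt(1 - alpha / 2, df2) * se
  structure(list(
    stats = st, mst = mst, mse = mse,
    f_stat = f_stat, df = c(1, df2), t_stat = t_stat,
    adjusted_diff = adjusted_diff, se = se,
    ci = c(adjusted_diff - half, adjusted_diff + half),
    p = p, alpha = alpha
  ), class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("ANCOVA adjusted group comparison\n")
  cat(sprintf("  adjusted difference (group 1 - group 2) = %.3f (se %.3f)\n",
              x$adjusted_diff, x$se))
  cat(sprintf("  %.0f%% CI [%.3f, %.3f]\n", 100 * (1 - x$alpha), x$ci[1], x$ci[2]))
  cat(sprintf("  F(%d, %d) = %.3f, t(%d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$f_stat, x$df[2], x$t_stat, x$p))
  invisible(x)
}

# one-way ANOVA F for two equal-size groups of values
oneway_f2 <- function(v1, v2) {
  n <- length(v1)
  m1 <- mean(v1); m2 <- mean(v2)
  ssb <- (n / 2) * (m1 - m2)^2
  msw <- (sum((v1 - m1)^2) + sum((v2 - m2)^2)) / (2 * (n - 1))
  df2 <- 2 * (n - 1)
  if (msw > 0) {
    f_stat <- ssb / msw
    p <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  } else if (ssb > 0) {
    f_stat <- Inf; p <- 0
  } else {
    f_stat <- 0; p <- 1
  }
  structure(list(f_stat = f_stat, df = c(1, df2), p = p),
            class = "ancova_comparator")
}

#' @export
print.ancova_comparator <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n",
              switch(x$analysis, gain_score = "Gain-score ANOVA",
                     anova_y = "ANOVA of outcome only", "Comparator ANOVA"),
              x$df[1], x$df[2], x$f_stat, x$p))
  invisible(x)
}

#' Gain-score (change-score) analysis
#'
#' One-way ANOVA comparing the per-unit gains `d = y - x` between the two
#' groups; tests the marginal hypothesis that the mean gains are equal
#' (\eqn{\Delta\mu_y = \Delta\mu_x}), which differs from the ANCOVA null
#' unless the design is randomized or beta = 1. Covariate and outcome must be
#' commensurate (e.g. pre/post measurements); this is the caller's
#' responsibility and is not checked. df are (1, 2(n-1)).
#'
#' @param sample A [two_group_sample()].
#' @return An `"ancova_comparator"` with `analysis = "gain_score"`.
#' @export
gain_score_test <- function(sample) {
  if (!inherits(sample, "two_group_sample"))
    stop("'sample' must be a 'two_group_sample' object", call. = FALSE)
  out <- oneway_f2(sample$y1 - sample$x1, sample$y2 - sample$x2)
  out$analysis <- "gain_score"
  out
}

#' ANOVA of the outcome, ignoring the covariate
#'
#' One-way ANOVA of y alone (equivalent to the squared two-sample t test);
#' tests the marginal hypothesis \eqn{\Delta\mu_y = 0}. df are (1, 2(n-1)).
#'
#' @param sample A [two_group_sample()].
#' @return An `"ancova_comparator"` with `analysis = "anova_y"`.
#' @export
anova_y_test <- function(sample) {
  if (!inherits(sample, "two_group_sample"))
    stop("'sample' must be a 'two_group_sample' object", call. = FALSE)
  out <- oneway_f2(sample$y1, sample$y2)
  out$analysis <- "anova_y"
  out
}

#' Covariate imbalance advisory
#'
#' Rule of thumb: for n > 5 an imbalance statistic f > 5 suggests the sample
#' covariate means differ by more than chance. Advisory only -- it never
#' alters the inference.
#'
#' @param stats An `"ancova_sample_stats"` object.
#' @return `TRUE` iff `n > 5` and `f > 5` (both strict).
#' @export
imbalance_warning <- function(stats) {
  if (!inherits(stats, "ancova_sample_stats"))
    stop("'stats' must be an 'ancova_sample_stats' object", call. = FALSE)
  stats$n > 5 && stats$f > 5
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number strictly inside (0, 1)", call. = FALSE)
  invisible(alpha)
}
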