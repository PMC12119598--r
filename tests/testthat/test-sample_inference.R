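test_that("worked-example summary statistics are reproduced exactly", {
  st <- sample_statistics(example_sample())
  expect_equal(st$s_xx, 2366)
  expect_equal(st$s_yy, 744)
  expect_equal(st$s_xy, 1143)
  expect_equal(st$delta_x_bar, -1)
  expect_equal(st$delta_y_bar, 11)
  expect_equal(round(st$b, 3), 0.483)
  expect_equal(round(st$r2, 3), 0.742)
  expect_equal(st$f, 20 / 2366, tolerance = 1e-12)
  # the two equivalent expressions for f agree
  expect_equal(st$f, (st$n / 2) * st$d_p^2, tolerance = 1e-10)
})

test_that("sums of squares are pooled within groups, by hand on a tiny sample", {
  s <- two_group_sample(x1 = c(0, 1, 2), y1 = c(0, 1, 2),
                        x2 = c(0, 1, 2), y2 = c(1, 2, 3))
  st <- sample_statistics(s)
  expect_equal(st$s_xx, 4)
  expect_equal(st$s_xy, 4)
  expect_equal(st$s_yy, 4)
  expect_equal(st$b, 1)
  expect_equal(st$r2, 1)
  expect_equal(st$delta_x_bar, 0)   # both groups share the x values {0, 1, 2}
  expect_equal(st$delta_y_bar, -1)
  expect_equal(st$f, 0)
})

test_that("perfectly linear data give b = 1, r2 = 1; degenerate covariate errors", {
  set.seed(1)
  x1 <- rnorm(6); x2 <- rnorm(6)
  st <- sample_statistics(two_group_sample(x1, x1, x2, x2))
  expect_equal(st$b, 1)
  expect_equal(st$r2, 1)
  expect_error(
    sample_statistics(two_group_sample(rep(1, 4), rnorm(4), rep(2, 4), rnorm(4))),
    "degenerate covariate")
  # constant outcome: r2 guarded to 0
  st0 <- sample_statistics(two_group_sample(rnorm(4), rep(2, 4), rnorm(4), rep(5, 4)))
  expect_equal(st0$r2, 0)
})

test_that("the ANCOVA test reproduces the worked example", {
  fit <- ancova_test(example_sample(), alpha = 0.05)
  expect_equal(round(fit$adjusted_diff, 2), 11.48)
  expect_equal(round(fit$f_stat, 2), 12.02)
  expect_equal(fit$df, c(1, 7))
  # exact upper-tail probability, cross-checked against an independent
  # implementation of the F distribution; conventional reports round it up
  expect_equal(fit$p, 0.0104545, tolerance = 1e-5)
  # exact CI from the formulas; the printed-report values round to
  # [3.65, 19.32] (see the methods vignette on the 0.02 rounding note)
  expect_equal(fit$ci, c(3.650175, 19.316005), tolerance = 1e-6)
  expect_equal(fit$f_stat, fit$t_stat^2, tolerance = 1e-10)
})

test_that("both MST expressions agree and reduce correctly when covariate means are equal", {
  set.seed(3)
  for (i in 1:20) {
    s <- random_sample()
    st <- sample_statistics(s)
    fit <- ancova_test(s)
    n <- st$n
    mst_direct <- st$delta_y_bar - st$b * st$delta_x_bar
    mst_direct <- mst_direct^2 / ((2 / n) * (1 + (n / 2) * st$delta_x_bar^2 / st$s_xx))
    expect_equal(fit$mst, mst_direct, tolerance = 1e-10)
  }
  # balanced covariate means: MST reduces to (n/2) dy^2
  s <- two_group_sample(x1 = c(1, 2, 3, 6), y1 = c(2, 4, 3, 7),
                        x2 = c(6, 3, 2, 1), y2 = c(1, 1, 2, 2))
  st <- sample_statistics(s)
  expect_equal(st$delta_x_bar, 0)
  fit <- ancova_test(s)
  expect_equal(fit$mst, (st$n / 2) * st$delta_y_bar^2)
})

test_that("identical groups give a zero adjusted difference and p = 1", {
  x <- c(1.2, 5, 3, 8, 0.4)
  y <- c(2, 1, 4, 7, 3)
  fit <- ancova_test(two_group_sample(x, y, x, y))
  expect_equal(fit$adjusted_diff, 0)
  expect_equal(fit$f_stat, 0)
  expect_equal(fit$p, 1)
})

test_that("F equals t squared and the CI/p duality holds on fuzzed samples", {
  set.seed(11)
  for (i in 1:1000) {
    fit <- ancova_test(random_sample(), alpha = 0.05)
    expect_lt(abs(fit$f_stat - fit$t_stat^2),
              1e-10 * max(fit$f_stat, .Machine$double.eps))
  }
  set.seed(12)
  for (i in 1:50) {
    s <- random_sample()
    for (a in c(0.01, 0.05, 0.10)) {
      fit <- ancova_test(s, alpha = a)
      expect_identical(fit$ci[1] > 0 || fit$ci[2] < 0, fit$p < a)
    }
  }
})

test_that("inference is invariant to covariate location/scale and to linear y-contamination", {
  set.seed(13)
  for (i in 1:25) {
    s <- random_sample()
    fit <- ancova_test(s)
    shift <- stats::runif(1, -10, 10)
    scale <- stats::runif(1, 0.1, 10)
    s_shift <- two_group_sample(s$x1 + shift, s$y1, s$x2 + shift, s$y2)
    s_scale <- two_group_sample(s$x1 * scale, s$y1, s$x2 * scale, s$y2)
    fit_shift <- ancova_test(s_shift)
    fit_scale <- ancova_test(s_scale)
    expect_equal(fit_shift$f_stat, fit$f_stat, tolerance = 1e-9)
    expect_equal(fit_shift$p, fit$p, tolerance = 1e-9)
    expect_equal(fit_shift$adjusted_diff, fit$adjusted_diff, tolerance = 1e-9)
    expect_equal(fit_scale$f_stat, fit$f_stat, tolerance = 1e-9)
    expect_equal(sample_statistics(s_scale)$r2, sample_statistics(s)$r2,
                 tolerance = 1e-9)
    # y <- y + c x is absorbed entirely by the slope adjustment
    cc <- stats::runif(1, -3, 3)
    s_lin <- two_group_sample(s$x1, s$y1 + cc * s$x1, s$x2, s$y2 + cc * s$x2)
    expect_equal(ancova_test(s_lin)$adjusted_diff, fit$adjusted_diff,
                 tolerance = 1e-8)
  }
})

test_that("adjusted difference and se match a least-squares fit by explicit normal equations", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_sample()
    n <- s$n
    # y ~ intercept + group indicator + covariate, solved from X'X directly
    g <- rep(c(1, 0), each = n)
    x <- c(s$x1, s$x2)
    y <- c(s$y1, s$y2)
    X <- cbind(1, g, x)
    XtX_inv <- solve(crossprod(X))
    coefs <- XtX_inv %*% crossprod(X, y)
    rss <- sum((y - X %*% coefs)^2)
    se_g <- sqrt(rss / (2 * n - 3) * XtX_inv[2, 2])
    fit <- ancova_test(s)
    expect_equal(fit$adjusted_diff, as.numeric(coefs[2, 1]), tolerance = 1e-9)
    expect_equal(fit$se, se_g, tolerance = 1e-9)
  }
})

test_that("gain-score ANOVA matches the worked example and a hand computation", {
  s <- example_sample()
  gain <- gain_score_test(s)
  expect_equal(gain$df, c(1, 8))
  # hand ANOVA on the gains: SSB = 360, MSW = 103
  expect_equal(gain$f_stat, 360 / 103, tolerance = 1e-12)
  expect_equal(round(gain$f_stat, 2), 3.50)
  expect_equal(gain$p, 0.099, tolerance = 0.02)  # display value derives from rounded F
  # all gains zero: no signal, no noise
  x <- c(1, 2, 3, 9)
  z <- gain_score_test(two_group_sample(x, x, x + 1, x + 1))
  expect_equal(z$f_stat, 0)
  expect_equal(z$p, 1)
})

test_that("ANOVA of the outcome alone matches the worked example", {
  s <- example_sample()
  ay <- anova_y_test(s)
  expect_equal(ay$df, c(1, 8))
  expect_equal(ay$f_stat, 302.5 / 93, tolerance = 1e-12)  # SSB = 5*11^2/2, MSW = 744/8
  expect_equal(round(ay$f_stat, 2), 3.25)
  expect_equal(round(ay$p, 3), 0.109)
  # equal outcome means: F = 0
  y <- c(0, 1, 2)
  expect_equal(anova_y_test(two_group_sample(rnorm(3), y, rnorm(3), rev(y)))$f_stat, 0)
})

test_that("the imbalance advisory uses strict n > 5 and f > 5", {
  st <- sample_statistics(example_sample())
  expect_false(imbalance_warning(st))   # n = 5, f ~ 0.008
  st$n <- 10; st$f <- 6
  expect_true(imbalance_warning(st))
  st$f <- 5
  expect_false(imbalance_warning(st))
  st$n <- 5; st$f <- 100
  expect_false(imbalance_warning(st))
})

test_that("sample construction rejects unequal sizes, tiny n, and non-finite values", {
  expect_error(two_group_sample(1:5, 1:5, 1:4, 1:4), "equal size")
  expect_error(two_group_sample(1:2, 1:2, 1:2, 1:2), "at least 3")
  expect_error(two_group_sample(c(1, 2, NA), 1:3, 1:3, 1:3), "finite")
})
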