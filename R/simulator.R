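#' Monte Carlo simulation configuration
#'
#' Bundles everything a seeded rejection-rate simulation needs. Under
#' `design = "random"` both covariate and outcome are drawn from the
#' bivariate-normal model per replication (appropriate for randomized and
#' observational studies alike; they differ only through the model's
#' delta_mu_x). Under `design = "fixed_x"` the covariate configuration in
#' `fixed_x_values` is reused in every replication and only the outcomes are
#' drawn from the conditional normal.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size (>= 3).
#' @param replications Number of Monte Carlo replications (>= 1).
#' @param seed Integer seed; identical configs give bit-identical results.
#' @param design `"random"` or `"fixed_x"`.
#' @param fixed_x_values List of two numeric vectors of length n (the fixed
#'   covariate values per group); required iff `design == "fixed_x"`.
#' @param analysis `"ancova"`, `"gain"` or `"anova_y"`.
#' @param alpha Significance level in (0,1).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(model, n, replications, seed,
                              design = c("random", "fixed_x"),
                              fixed_x_values = NULL,
                              analysis = c("ancova", "gain", "anova_y"),
                              alpha = 0.05) {
  stopifnot_model(model)
  check_n(n)
  check_alpha(alpha)
  design <- match.arg(design)
  analysis <- match.arg(analysis)
  if (!is.numeric(replications) || length(replications) != 1L ||
      replications < 1 || replications != as.integer(replications))
    stop("'replications' must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (design == "fixed_x") {
    if (!is.list(fixed_x_values) || length(fixed_x_values) != 2L ||
        length(fixed_x_values[[1]]) != n || length(fixed_x_values[[2]]) != n ||
        !all(is.finite(unlist(fixed_x_values))))
      stop("design 'fixed_x' requires 'fixed_x_values': a list of two finite numeric vectors of length n",
           call. = FALSE)
  } else {
    fixed_x_values <- NULL
  }
  structure(list(model = model, n = as.integer(n),
                 replications = as.integer(replications),
                 seed = as.integer(seed), design = design,
                 fixed_x_values = fixed_x_values,
                 analysis = analysis, alpha = alpha),
            class = "simulation_config")
}

#' Draw one sample from the bivariate-normal ANCOVA model
#'
#' Draws n (x, y) pairs per group from the group's bivariate normal with the
#' common covariance matrix, via its Cholesky factor:
#' `x = mu_x + sigma_x z1`, `y = mu_y + sigma_y (rho z1 + sqrt(1-rho^2) z2)`.
#' Uses the current RNG state; call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size (>= 3).
#' @return A [two_group_sample()].
#' @export
draw_sample <- function(model, n) {
  stopifnot_model(model)
  check_n(n)
  z1 <- stats::rnorm(2 * n)
  z2 <- stats::rnorm(2 * n)
  a <- model$rho
  b <- sqrt(1 - model$rho^2)
  x <- c(model$mu_x1 + model$sigma_x * z1[1:n],
         model$mu_x2 + model$sigma_x * z1[(n + 1):(2 * n)])
  y <- c(model$mu_y1, model$mu_y2)[rep(1:2, each = n)] +
    model$sigma_y * (a * z1 + b * z2)
  two_group_sample(x[1:n], y[1:n], x[(n + 1):(2 * n)], y[(n + 1):(2 * n)])
}

#' Draw outcomes conditional on fixed covariate values
#'
#' Copies the supplied covariate values verbatim and draws each outcome from
#' its conditional normal: mean [conditional_mean()] at that x, standard
#' deviation \eqn{\sigma_e = \sqrt{(1-\rho^2)}\,\sigma_y}. Uses the current
#' RNG state.
#'
#' @param model An [ancova_model()].
#' @param x1,x2 Fixed covariate values for groups 1 and 2 (length n each).
#' @return A [two_group_sample()].
#' @export
draw_conditional_sample <- function(model, x1, x2) {
  stopifnot_model(model)
  n <- length(x1)
  if (length(x2) != n || n < 3 || !all(is.finite(c(x1, x2))))
    stop("'x1' and 'x2' must be finite numeric vectors of equal length >= 3",
         call. = FALSE)
  sigma_e <- sqrt(model$sigma_e2)
  y1 <- conditional_mean(model, 1, x1) + sigma_e * stats::rnorm(n)
  y2 <- conditional_mean(model, 2, x2) + sigma_e * stats::rnorm(n)
  two_group_sample(x1, y1, x2, y2)
}

# Vectorized replication engine. X*, Y* are R x n matrices (one row per
# replication). Returns list(p = p-values, degenerate = logical).
mc_pvalues <- function(X1, Y1, X2, Y2, analysis) {
  n <- ncol(X1)
  if (analysis == "ancova") {
    mx1 <- rowMeans(X1); mx2 <- rowMeans(X2)
    my1 <- rowMeans(Y1); my2 <- rowMeans(Y2)
    dX1 <- X1 - mx1; dX2 <- X2 - mx2
    dY1 <- Y1 - my1; dY2 <- Y2 - my2
    s_xx <- rowSums(dX1^2) + rowSums(dX2^2)
    s_yy <- rowSums(dY1^2) + rowSums(dY2^2)
    s_xy <- rowSums(dX1 * dY1) + rowSums(dX2 * dY2)
    degenerate <- s_xx == 0
    s_xx[degenerate] <- NA_real_
    b <- s_xy / s_xx
    r2 <- ifelse(s_yy == 0, 0, s_xy^2 / (s_xx * s_yy))
    dx <- mx1 - mx2
    adj <- (my1 - my2) - b * dx
    f <- n * (n - 1) * dx^2 / s_xx
    mst <- n * (n - 1) * adj^2 / (2 * (n - 1) + f)
    mse <- (1 - r2) * s_yy / (2 * n - 3)
    p <- ifelse(mse > 0,
                stats::pf(mst / mse, 1, 2 * n - 3, lower.tail = FALSE),
                ifelse(mst > 0, 0, 1))
  } else {
    V1 <- if (analysis == "gain") Y1 - X1 else Y1
    V2 <- if (analysis == "gain") Y2 - X2 else Y2
    m1 <- rowMeans(V1); m2 <- rowMeans(V2)
    ssb <- (n / 2) * (m1 - m2)^2
    msw <- (rowSums((V1 - m1)^2) + rowSums((V2 - m2)^2)) / (2 * (n - 1))
    degenerate <- rep(FALSE, nrow(X1))
    p <- ifelse(msw > 0,
                stats::pf(ssb / msw, 1, 2 * (n - 1), lower.tail = FALSE),
                ifelse(ssb > 0, 0, 1))
  }
  list(p = p, degenerate = degenerate)
}

#' Monte Carlo rejection rate
#'
#' Runs the configured analysis on `replications` seeded samples and reports
#' the proportion rejecting at level alpha, with its binomial Monte Carlo
#' standard error `sqrt(p(1-p)/R)`. Replications with a degenerate covariate
#' (s_xx = 0; impossible under the continuous model, possible with
#' pathological fixed covariates) are counted and reported separately, never
#' silently dropped: the rate is taken over the valid replications.
#'
#' @param config A [simulation_config()].
#' @return An object of class `"ancova_mc"`: `rate`, `se`, `rejections`,
#'   `replications`, `degenerate`, plus the config echo fields `analysis`,
#'   `design`, `alpha`, `seed`, `n`.
#' @export
empirical_power <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a 'simulation_config' object", call. = FALSE)
  set.seed(config$seed)
  R <- config$replications
  n <- config$n
  m <- config$model
  if (config$design == "random") {
    Z1 <- matrix(stats::rnorm(R * 2L * n), R, 2L * n)
    Z2 <- matrix(stats::rnorm(R * 2L * n), R, 2L * n)
    a <- m$rho; bb <- sqrt(1 - m$rho^2)
    X1 <- m$mu_x1 + m$sigma_x * Z1[, 1:n, drop = FALSE]
    X2 <- m$mu_x2 + m$sigma_x * Z1[, (n + 1):(2 * n), drop = FALSE]
    Y1 <- m$mu_y1 + m$sigma_y * (a * Z1[, 1:n, drop = FALSE] +
                                   bb * Z2[, 1:n, drop = FALSE])
    Y2 <- m$mu_y2 + m$sigma_y * (a * Z1[, (n + 1):(2 * n), drop = FALSE] +
                                   bb * Z2[, (n + 1):(2 * n), drop = FALSE])
  } else {
    sigma_e <- sqrt(m$sigma_e2)
    X1 <- matrix(config$fixed_x_values[[1]], R, n, byrow = TRUE)
    X2 <- matrix(config$fixed_x_values[[2]], R, n, byrow = TRUE)
    Y1 <- matrix(conditional_mean(m, 1, config$fixed_x_values[[1]]),
                 R, n, byrow = TRUE) + sigma_e * matrix(stats::rnorm(R * n), R, n)
    Y2 <- matrix(conditional_mean(m, 2, config$fixed_x_values[[2]]),
                 R, n, byrow = TRUE) + sigma_e * matrix(stats::rnorm(R * n), R, n)
  }
  res <- mc_pvalues(X1, Y1, X2, Y2, config$analysis)
  valid <- !res$degenerate
  rejections <- sum(res$p[valid] < config$alpha)
  n_valid <- sum(valid)
  rate <- rejections / n_valid
  structure(list(
    rate = rate,
    se = sqrt(rate * (1 - rate) / n_valid),
    rejections = rejections,
    replications = R,
    degenerate = R - n_valid,
    analysis = config$analysis, design = config$design,
    alpha = config$alpha, seed = config$seed, n = n
  ), class = "ancova_mc")
}

#' @export
print.ancova_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo rejection rate (%s, %s design)\n", x$analysis, x$design))
  cat(sprintf("  rate = %.4f (MC se %.4f), %d / %d rejections at alpha = %g\n",
              x$rate, x$se, x$rejections, x$replications - x$degenerate, x$alpha))
  if (x$degenerate > 0)
    cat(sprintf("  %d degenerate replication(s) (s_xx = 0) excluded and reported here\n",
                x$degenerate))
  cat(sprintf("  n = %d per group, seed = %d\n", x$n, x$seed))
  invisible(x)
}

#' Sampling distribution of the covariate imbalance statistic
#'
#' Simulates the imbalance statistic f = n(n-1) (dx)^2 / s_xx over
#' replications of the covariate draw and compares it with its exact
#' noncentral F(1, 2(n-1), lambda) law via the Kolmogorov-Smirnov distance.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @param replications Number of replications.
#' @param seed Integer seed.
#' @return A list: `f` (simulated values), `ks` (KS distance to the exact
#'   law), `lambda`, `df` (the pair (1, 2(n-1))).
#' @export
empirical_f_distribution <- function(model, n, replications, seed) {
  stopifnot_model(model)
  check_n(n)
  set.seed(seed)
  R <- as.integer(replications)
  X1 <- matrix(stats::rnorm(R * n, model$mu_x1, model$sigma_x), R, n)
  X2 <- matrix(stats::rnorm(R * n, model$mu_x2, model$sigma_x), R, n)
  mx1 <- rowMeans(X1); mx2 <- rowMeans(X2)
  s_xx <- rowSums((X1 - mx1)^2) + rowSums((X2 - mx2)^2)
  f <- n * (n - 1) * (mx1 - mx2)^2 / s_xx
  lambda <- lambda_ncp(model, n)
  fs <- sort(f)
  theo <- suppressWarnings(stats::pf(fs, 1, 2 * (n - 1), ncp = lambda))
  emp_hi <- seq_len(R) / R
  emp_lo <- (seq_len(R) - 1) / R
  ks <- max(pmax(abs(emp_hi - theo), abs(emp_lo - theo)))
  list(f = f, ks = ks, lambda = lambda, df = c(1, 2 * (n - 1)))
}
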