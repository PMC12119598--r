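#' Noncentrality of the covariate-imbalance statistic
#'
#' Under the bivariate-normal model the imbalance statistic f follows a
#' noncentral F distribution with df (1, 2(n-1)) and noncentrality
#' \eqn{\lambda = (n/2) (\Delta\mu_x / \sigma_x)^2}. Randomized designs have
#' \eqn{\Delta\mu_x = 0} and hence \eqn{\lambda = 0} (central F).
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @return The noncentrality parameter lambda (>= 0).
#' @export
lambda_ncp <- function(model, n) {
  stopifnot_model(model)
  check_n(n)
  (n / 2) * (model$delta_mu_x / model$sigma_x)^2
}

#' Conditional noncentrality of the ANCOVA F statistic
#'
#' Given the covariate imbalance f, the ANCOVA F statistic follows a
#' noncentral F with df (1, 2n-3) and noncentrality
#' \deqn{k(f) = n(n-1)\left(\frac{\Delta\mu_y - \beta\Delta\mu_x}{\sigma_e}\right)^2
#'   / (2(n-1) + f).}
#' k is strictly decreasing in f when the adjusted difference is nonzero,
#' and identically zero under the null regardless of f. At f = 0 it reduces
#' to the standard form \eqn{(n/2)(\mathrm{adjusted\ delta}/\sigma_e)^2}.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @param f Imbalance statistic value(s), >= 0; vectorized.
#' @return Noncentrality value(s) k(f) >= 0.
#' @export
k_of_f <- function(model, n, f) {
  stopifnot_model(model)
  check_n(n)
  if (any(f < 0)) stop("'f' must be nonnegative", call. = FALSE)
  n * (n - 1) * (model$adjusted_delta^2 / model$sigma_e2) / (2 * (n - 1) + f)
}

#' Conditional (fixed-covariate) ANCOVA power
#'
#' Power of the level-alpha ANCOVA F test given a fixed covariate
#' configuration summarized by the imbalance statistic f:
#' \eqn{P(F_{1,2n-3,k(f)} > F_{1,2n-3}(1-\alpha))}. A controlled design
#' (covariate values fixed with equal group means) corresponds to f = 0.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size (>= 3).
#' @param alpha Significance level in (0,1).
#' @param f Fixed imbalance value >= 0.
#' @return Rejection probability; equals alpha when the null holds.
#' @export
conditional_power <- function(model, n, alpha, f) {
  check_alpha(alpha)
  k <- k_of_f(model, n, f)
  df2 <- 2 * n - 3
  crit <- stats::qf(1 - alpha, 1, df2)
  suppressWarnings(stats::pf(crit, 1, df2, ncp = k, lower.tail = FALSE))
}

# Expectation of g(f) where f ~ noncentral F(1, 2(n-1), lambda).
# Uses the representation f = T^2 with T ~ noncentral t_{2(n-1)}(sqrt(lambda)):
# the integrand in t is smooth on (0, Inf), avoiding the f^(-1/2) endpoint
# singularity of the df1 = 1 density. g must be vectorized.
mixture_expectation <- function(g, n, lambda, rel.tol = 1e-10, abs.tol = 1e-12) {
  m <- 2 * (n - 1)
  delta <- sqrt(lambda)
  integrand <- function(t)
    g(t^2) * (stats::dt(t, m, ncp = delta) + stats::dt(-t, m, ncp = delta))
  res <- suppressWarnings(
    stats::integrate(integrand, 0, Inf, rel.tol = rel.tol, abs.tol = abs.tol,
                     subdivisions = 1000L, stop.on.error = FALSE)
  )
  if (res$message != "OK")
    stop(sprintf("quadrature over the imbalance mixture failed: %s (n = %d, lambda = %g, abs.error = %g)",
                 res$message, n, lambda, res$abs.error), call. = FALSE)
  res$value
}

#' Unconditional (random-covariate) ANCOVA power
#'
#' Exact power of the level-alpha ANCOVA F test when the covariate is random:
#' the test statistic follows a mixture of noncentral F(1, 2n-3, k(f))
#' distributions whose mixing distribution is itself a noncentral
#' F(1, 2(n-1), lambda) -- the distribution of the covariate imbalance f.
#' Power is
#' \deqn{1 - \int_0^\infty P(F_{1,2n-3,k(f)} \le F_{crit})\, q_{1,2(n-1),\lambda}(f)\, df,}
#' computed by adaptive quadrature after substituting f = t^2 with t a
#' noncentral t variate (smooth integrand, absolute tolerance below 1e-7).
#' Equals alpha exactly when the null \eqn{\Delta\mu_y = \beta\Delta\mu_x}
#' holds, since then k(f) = 0 for every f.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size (>= 3).
#' @param alpha Significance level in (0,1).
#' @return Rejection probability in [alpha, 1).
#' @export
unconditional_power <- function(model, n, alpha) {
  check_alpha(alpha)
  stopifnot_model(model)
  check_n(n)
  df2 <- 2 * n - 3
  crit <- stats::qf(1 - alpha, 1, df2)
  lambda <- lambda_ncp(model, n)
  reject_given_f <- function(f)
    suppressWarnings(stats::pf(crit, 1, df2, ncp = k_of_f(model, n, f),
                               lower.tail = FALSE))
  mixture_expectation(reject_given_f, n, lambda)
}

#' Expected adjusted treatment mean square
#'
#' Conditional on the covariate imbalance f,
#' \deqn{E[MST | f] = (\Delta\mu_y - \beta\Delta\mu_x)^2\, n(n-1)/(2(n-1)+f) + \sigma_e^2;}
#' the unconditional form integrates the first term over the noncentral-F
#' density of f. Under the null both reduce to the error variance
#' \eqn{\sigma_e^2}; when \eqn{\Delta\mu_x = 0} the unconditional value has
#' the closed form \eqn{\sigma_e^2 + n(n-1)/(2n-1)\,\Delta\mu_y^2}.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @param f Imbalance value (>= 0) for the conditional form.
#' @return Expected MST in outcome-variance units.
#' @export
expected_mst_given_f <- function(model, n, f) {
  stopifnot_model(model)
  check_n(n)
  if (any(f < 0)) stop("'f' must be nonnegative", call. = FALSE)
  model$adjusted_delta^2 * n * (n - 1) / (2 * (n - 1) + f) + model$sigma_e2
}

#' @rdname expected_mst_given_f
#' @export
expected_mst <- function(model, n) {
  stopifnot_model(model)
  check_n(n)
  lambda <- lambda_ncp(model, n)
  mult <- mixture_expectation(function(f) n * (n - 1) / (2 * (n - 1) + f),
                              n, lambda)
  model$adjusted_delta^2 * mult + model$sigma_e2
}

#' Power of the gain-score analysis
#'
#' The two-group ANOVA of gains d = y - x has df (1, 2(n-1)) and exact
#' noncentrality
#' \deqn{\theta = (n/2)\left(\frac{\Delta\mu_y - \Delta\mu_x}{\sigma_{y-x}}\right)^2,
#'   \qquad \sigma_{y-x}^2 = \sigma_x^2 + \sigma_y^2 - 2\rho\sigma_x\sigma_y.}
#' Its power generally decreases as rho decreases (the gain variance grows).
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @param alpha Significance level in (0,1).
#' @return Rejection probability; equals alpha when
#'   \eqn{\Delta\mu_y = \Delta\mu_x}.
#' @export
gain_score_power <- function(model, n, alpha) {
  check_alpha(alpha)
  stopifnot_model(model)
  check_n(n)
  sigma_d2 <- model$sigma_x^2 + model$sigma_y^2 -
    2 * model$rho * model$sigma_x * model$sigma_y
  if (sigma_d2 <= 0)
    stop("gain-score variance is zero (rho = 1 with sigma_x = sigma_y)", call. = FALSE)
  theta <- (n / 2) * (model$delta_mu_y - model$delta_mu_x)^2 / sigma_d2
  df2 <- 2 * (n - 1)
  crit <- stats::qf(1 - alpha, 1, df2)
  suppressWarnings(stats::pf(crit, 1, df2, ncp = theta, lower.tail = FALSE))
}

#' Power of the covariate-ignoring t test
#'
#' Power of the two-sample t test (equivalently the F(1, 2(n-1)) ANOVA) of
#' the marginal outcome means, with noncentrality
#' \eqn{(n/2)(\Delta\mu_y/\sigma_y)^2}. Independent of rho and of the
#' covariate means.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size.
#' @param alpha Significance level in (0,1).
#' @return Rejection probability.
#' @export
marginal_ttest_power <- function(model, n, alpha) {
  check_alpha(alpha)
  stopifnot_model(model)
  check_n(n)
  ncp <- (n / 2) * (model$delta_mu_y / model$sigma_y)^2
  df2 <- 2 * (n - 1)
  crit <- stats::qf(1 - alpha, 1, df2)
  suppressWarnings(stats::pf(crit, 1, df2, ncp = ncp, lower.tail = FALSE))
}

#' Power request: design and analysis family for a planned study
#'
#' Validates and bundles everything needed to compute power: the population
#' model, per-group size, level, design and analysis family.
#' Designs: `"controlled"` (covariate values fixed by the investigator with
#' equal group means, so f = 0 in every sample), `"randomized"` (random
#' allocation, so delta_mu_x must be 0 and lambda = 0), `"observational"`
#' (intact groups, delta_mu_x unrestricted), and `"fixed_x"` (covariates
#' fixed at an arbitrary configuration supplying the imbalance `fixed_f`).
#' Other things equal, ANCOVA power is largest under controlled, intermediate
#' under randomized, and lowest under observational designs.
#'
#' @param model An [ancova_model()].
#' @param n Per-group sample size (>= 3).
#' @param alpha Significance level in (0,1).
#' @param design One of `"controlled"`, `"randomized"`, `"observational"`,
#'   `"fixed_x"`.
#' @param fixed_f Nonnegative imbalance value; required iff
#'   `design == "fixed_x"` (a controlled design implies `fixed_f = 0`).
#' @param analysis One of `"ancova"`, `"gain"`, `"anova_y"`.
#' @return An object of class `"power_request"`.
#' @export
power_request <- function(model, n, alpha = 0.05,
                          design = c("randomized", "controlled",
                                     "observational", "fixed_x"),
                          fixed_f = NULL,
                          analysis = c("ancova", "gain", "anova_y")) {
  stopifnot_model(model)
  check_n(n)
  check_alpha(alpha)
  design <- match.arg(design)
  analysis <- match.arg(analysis)
  if (design == "randomized" && model$delta_mu_x != 0)
    stop("a randomized design implies delta_mu_x = 0; the supplied model has delta_mu_x = ",
         model$delta_mu_x, call. = FALSE)
  if (design == "fixed_x") {
    if (is.null(fixed_f) || !is.numeric(fixed_f) || length(fixed_f) != 1L ||
        !is.finite(fixed_f) || fixed_f < 0)
      stop("design 'fixed_x' requires a single nonnegative 'fixed_f'", call. = FALSE)
  } else if (design == "controlled") {
    fixed_f <- 0
  } else {
    fixed_f <- NULL
  }
  structure(list(model = model, n = as.integer(n), alpha = alpha,
                 design = design, fixed_f = fixed_f, analysis = analysis),
            class = "power_request")
}

#' Compute power for a request
#'
#' Dispatches on the design and analysis family: ANCOVA power is conditional
#' (noncentral F at `k(fixed_f)`) for controlled / fixed-covariate designs
#' and unconditional (noncentral-F mixture) for randomized / observational
#' designs; gain-score and outcome-only analyses use their exact marginal
#' noncentral-F forms, which do not involve the covariate imbalance.
#'
#' @param request A [power_request()].
#' @return Rejection probability.
#' @export
compute_power <- function(request) {
  if (!inherits(request, "power_request"))
    stop("'request' must be a 'power_request' object", call. = FALSE)
  with(request, switch(
    analysis,
    ancova = if (design %in% c("controlled", "fixed_x"))
      conditional_power(model, n, alpha, fixed_f)
    else
      unconditional_power(model, n, alpha),
    gain = gain_score_power(model, n, alpha),
    anova_y = marginal_ttest_power(model, n, alpha)
  ))
}

#' @export
print.power_request <- function(x, ...) {
  cat(sprintf("Power request: analysis = %s, design = %s, n = %d, alpha = %g%s\n",
              x$analysis, x$design, x$n, x$alpha,
              if (!is.null(x$fixed_f)) sprintf(", fixed f = %g", x$fixed_f) else ""))
  print(x$model)
  invisible(x)
}

#' Power curve over a parameter grid
#'
#' Re-evaluates the power of a request along a grid of one parameter
#' (`"rho"`, `"delta_mu_y"`, `"delta_mu_x"`, `"n"` or `"alpha"`). Mean-
#' difference sweeps move mu_x1 / mu_y1 with the group-2 means held fixed.
#' Each grid point is validated like the original request, so e.g. sweeping
#' `delta_mu_x` away from 0 under a randomized design is rejected.
#'
#' @param request A [power_request()].
#' @param sweep Parameter name to sweep.
#' @param grid Numeric grid of values for that parameter (may be empty).
#' @return A data frame with columns: the swept parameter, `power`,
#'   `analysis`, `design`; one row per grid value, in grid order.
#' @export
power_curve <- function(request, sweep, grid) {
  if (!inherits(request, "power_request"))
    stop("'request' must be a 'power_request' object", call. = FALSE)
  ok <- c("rho", "delta_mu_y", "delta_mu_x", "n", "alpha")
  if (!(is.character(sweep) && length(sweep) == 1L && sweep %in% ok))
    stop("'sweep' must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  grid <- as.numeric(grid)
  pw <- vapply(grid, function(v) {
    m <- request$model
    newmod <- switch(sweep,
      rho = ancova_model(m$mu_x1, m$mu_x2, m$mu_y1, m$mu_y2,
                         m$sigma_x, m$sigma_y, v),
      delta_mu_y = ancova_model(m$mu_x1, m$mu_x2, m$mu_y2 + v, m$mu_y2,
                                m$sigma_x, m$sigma_y, m$rho),
      delta_mu_x = ancova_model(m$mu_x2 + v, m$mu_x2, m$mu_y1, m$mu_y2,
                                m$sigma_x, m$sigma_y, m$rho),
      m)
    n <- if (sweep == "n") v else request$n
    alpha <- if (sweep == "alpha") v else request$alpha
    compute_power(power_request(newmod, n, alpha, design = request$design,
                                fixed_f = request$fixed_f,
                                analysis = request$analysis))
  }, numeric(1))
  out <- data.frame(grid, power = pw,
                    analysis = rep(request$analysis, length(grid)),
                    design = rep(request$design, length(grid)),
                    stringsAsFactors = FALSE)
  names(out)[1] <- sweep
  out
}

#' Smallest sample size reaching a target power
#'
#' Monotone search (geometric bracket doubling, then integer bisection) for
#' the smallest per-group n >= 3 whose power under the requested design
#' reaches `target_power`; power is increasing in n because every
#' noncentrality parameter grows with n.
#'
#' @param model A non-null [ancova_model()].
#' @param alpha Significance level in (0,1).
#' @param target_power Target in (alpha, 1).
#' @param design Design mode as in [power_request()].
#' @param fixed_f Imbalance value for `design = "fixed_x"`.
#' @param analysis Analysis family as in [power_request()].
#' @param n_max Search bound (default 1e6); an unreachable target errors.
#' @return Smallest integer n with power(n) >= target_power.
#' @export
solve_sample_size <- function(model, alpha, target_power,
                              design = "randomized", fixed_f = NULL,
                              analysis = "ancova", n_max = 1e6) {
  check_alpha(alpha)
  if (!is.numeric(target_power) || length(target_power) != 1L ||
      target_power <= alpha || target_power >= 1)
    stop("'target_power' must lie strictly between alpha and 1", call. = FALSE)
  pow <- function(n)
    compute_power(power_request(model, n, alpha, design = design,
                                fixed_f = fixed_f, analysis = analysis))
  lo <- 3L
  if (pow(lo) >= target_power) return(lo)
  hi <- lo
  repeat {
    hi <- min(as.integer(2 * hi), as.integer(n_max))
    if (pow(hi) >= target_power) break
    if (hi >= n_max)
      stop(sprintf("target power %g not reachable below n = %g (power at bound: %g); is the model null?",
                   target_power, n_max, pow(hi)), call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

check_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 3 ||
      n != as.integer(n))
    stop("'n' must be a single integer >= 3", call. = FALSE)
  invisible(n)
}
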