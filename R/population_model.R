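#' Bivariate-normal ANCOVA population model
#'
#' Constructs the population model underlying the two-group analysis of
#' covariance with a random covariate: within each group the covariate
#' \eqn{x} and the outcome \eqn{y} follow a bivariate normal distribution
#' with a common covariance matrix across groups. The common within-group
#' regression slope is \eqn{\beta = \rho \sigma_y / \sigma_x}, the residual
#' (error) variance is \eqn{\sigma_e^2 = (1 - \rho^2)\sigma_y^2}, and the
#' adjusted population mean difference -- the vertical separation of the two
#' parallel group regression lines -- is
#' \eqn{\Delta\mu_y - \beta \Delta\mu_x}.
#'
#' @param mu_x1,mu_x2 Covariate population means of groups 1 and 2.
#' @param mu_y1,mu_y2 Outcome population means of groups 1 and 2.
#' @param sigma_x,sigma_y Within-group standard deviations (strictly
#'   positive, identical across groups).
#' @param rho Within-group correlation between covariate and outcome,
#'   strictly inside (-1, 1); \eqn{\rho = \pm 1} is rejected because it makes
#'   the error variance zero and the F statistic degenerate.
#'
#' @return An object of class `"ancova_model"`: a list with the seven input
#'   parameters plus the derived quantities `beta`, `sigma_e2`, `delta_mu_x`,
#'   `delta_mu_y` and `adjusted_delta`.
#'
#' @examples
#' m <- ancova_model(mu_x1 = 1, mu_x2 = 0, mu_y1 = 1, mu_y2 = 0,
#'                   sigma_x = 1, sigma_y = 1, rho = 0.6)
#' m$adjusted_delta  # 1 - 0.6 * 1 = 0.4
#' @export
ancova_model <- function(mu_x1, mu_x2, mu_y1, mu_y2, sigma_x, sigma_y, rho) {
  for (nm in c("mu_x1", "mu_x2", "mu_y1", "mu_y2", "sigma_x", "sigma_y", "rho")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (sigma_x <= 0 || sigma_y <= 0)
    stop("'sigma_x' and 'sigma_y' must be strictly positive", call. = FALSE)
  if (abs(rho) >= 1)
    stop("'rho' must lie strictly inside (-1, 1): rho = +/-1 gives zero error variance",
         call. = FALSE)
  beta <- rho * sigma_y / sigma_x
  model <- list(
    mu_x1 = mu_x1, mu_x2 = mu_x2, mu_y1 = mu_y1, mu_y2 = mu_y2,
    sigma_x = sigma_x, sigma_y = sigma_y, rho = rho,
    beta = beta,
    sigma_e2 = (1 - rho^2) * sigma_y^2,
    delta_mu_x = mu_x1 - mu_x2,
    delta_mu_y = mu_y1 - mu_y2,
    adjusted_delta = (mu_y1 - mu_y2) - beta * (mu_x1 - mu_x2)
  )
  class(model) <- "ancova_model"
  model
}

#' @export
print.ancova_model <- function(x, ...) {
  cat("Bivariate-normal ANCOVA population model\n")
  cat(sprintf("  group 1: mu_x = %g, mu_y = %g\n", x$mu_x1, x$mu_y1))
  cat(sprintf("  group 2: mu_x = %g, mu_y = %g\n", x$mu_x2, x$mu_y2))
  cat(sprintf("  sigma_x = %g, sigma_y = %g, rho = %g\n",
              x$sigma_x, x$sigma_y, x$rho))
  cat(sprintf("  slope beta = %g, error variance sigma_e^2 = %g\n",
              x$beta, x$sigma_e2))
  cat(sprintf("  adjusted mean difference = %g%s\n", x$adjusted_delta,
              if (null_holds(x)) "  (null model)" else ""))
  invisible(x)
}

stopifnot_model <- function(model) {
  if (!inherits(model, "ancova_model"))
    stop("'model' must be an 'ancova_model' object", call. = FALSE)
  invisible(model)
}

#' Conditional outcome mean given a covariate value
#'
#' Evaluates the population regression line of the requested group,
#' \eqn{(\mu_{yi} - \beta\mu_{xi}) + \beta x}. Because the two group lines
#' are parallel, the between-group difference at any `x` equals the model's
#' `adjusted_delta`.
#'
#' @param model An [ancova_model()].
#' @param group Group index, 1 or 2.
#' @param x Covariate value(s); vectorized.
#' @return Conditional mean(s) of the outcome.
#' @examples
#' m <- ancova_model(1, 0, 1, 0, 1, 1, 0.6)
#' conditional_mean(m, 1, 0.3) - conditional_mean(m, 2, 0.3)  # 0.4
#' @export
conditional_mean <- function(model, group, x) {
  stopifnot_model(model)
  if (!(length(group) == 1L && group %in% c(1, 2)))
    stop("'group' must be 1 or 2", call. = FALSE)
  mu_y <- if (group == 1) model$mu_y1 else model$mu_y2
  mu_x <- if (group == 1) model$mu_x1 else model$mu_x2
  (mu_y - model$beta * mu_x) + model$beta * x
}

#' Standardize an ANCOVA population model
#'
#' Re-expresses the model with \eqn{\mu_{x2} = \mu_{y2} = 0} and
#' \eqn{\sigma_x = \sigma_y = 1}: the group-mean differences become
#' standardized distances \eqn{\Delta\mu_x/\sigma_x} and
#' \eqn{\Delta\mu_y/\sigma_y}, the correlation is unchanged, and the slope of
#' the standardized model equals \eqn{\rho}. Significance and power are
#' invariant under this reduction, so only three effective parameters remain.
#'
#' @param model An [ancova_model()].
#' @return A standardized `"ancova_model"`.
#' @export
standardize <- function(model) {
  stopifnot_model(model)
  ancova_model(
    mu_x1 = model$delta_mu_x / model$sigma_x, mu_x2 = 0,
    mu_y1 = model$delta_mu_y / model$sigma_y, mu_y2 = 0,
    sigma_x = 1, sigma_y = 1, rho = model$rho
  )
}

#' Does the ANCOVA null hypothesis hold in the population?
#'
#' The null hypothesis of the adjusted group comparison is
#' \eqn{\Delta\mu_y = \beta\Delta\mu_x}, i.e. a zero adjusted mean
#' difference. Tested with a fixed absolute tolerance of 1e-12 (the quantity
#' is pure parameter arithmetic, so no sampling slack is needed).
#'
#' @param model An [ancova_model()].
#' @return `TRUE` iff `|adjusted_delta| <= 1e-12`.
#' @export
null_holds <- function(model) {
  stopifnot_model(model)
  abs(model$adjusted_delta) <= 1e-12
}
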