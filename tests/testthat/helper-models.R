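# Random valid population models for property-style tests.
random_model <- function() {
  ancova_model(
    mu_x1 = stats::runif(1, -3, 3), mu_x2 = stats::runif(1, -3, 3),
    mu_y1 = stats::runif(1, -3, 3), mu_y2 = stats::runif(1, -3, 3),
    sigma_x = stats::runif(1, 0.3, 3), sigma_y = stats::runif(1, 0.3, 3),
    rho = stats::runif(1, -0.9, 0.9)
  )
}

# Random nondegenerate two-group sample (continuous, so s_xx > 0 a.s.).
random_sample <- function(n = sample(3:12, 1)) {
  two_group_sample(stats::rnorm(n), stats::rnorm(n),
                   stats::rnorm(n), stats::rnorm(n))
}

# The fictitious worked-example data (groups of 5, pre/post-style).
example_sample <- function() {
  two_group_sample(
    x1 = c(43, 33, 19, 7, 53), y1 = c(44, 50, 37, 38, 61),
    x2 = c(52, 11, 22, 40, 35), y2 = c(45, 27, 26, 45, 32)
  )
}
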