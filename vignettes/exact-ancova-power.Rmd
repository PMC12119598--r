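---
title: "Exact power for the two-group ANCOVA with random covariates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact power for the two-group ANCOVA with random covariates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancovapower)
```

## The model

`ancovapower` implements exact inference and power analysis for the most
common analysis of covariance: two independent groups of equal size $n$, one
quantitative covariate $x$, one quantitative outcome $y$. Within each group,
$(x, y)$ is assumed bivariate normal with a covariance matrix that is
arbitrary but **identical across groups**: standard deviations $\sigma_x$,
$\sigma_y$ and correlation $\rho$. This forces a common within-group
regression slope $\beta = \rho\,\sigma_y/\sigma_x$, i.e. parallel group
regression lines, separated vertically by the *adjusted mean difference*

$$\Delta\mu_y - \beta\,\Delta\mu_x, \qquad
  \Delta\mu_y = \mu_{y1}-\mu_{y2},\quad \Delta\mu_x = \mu_{x1}-\mu_{x2}.$$

The ANCOVA null hypothesis is that this adjusted difference is zero:
$H_0\!: \Delta\mu_y = \beta\,\Delta\mu_x$. This is a hypothesis about
*conditional* means (the expected outcome difference at any fixed covariate
value), not about the marginal means $\Delta\mu_y$ that a plain $t$ test or a
gain-score analysis addresses — the distinction that drives everything else
in the package.

Crucially, the covariate is treated as **random**: every hypothetical
replication of the study draws new covariate values. A fixed-covariate
analysis is available as the conditional special case.

## Sample inference

From raw data, `sample_statistics()` computes pooled *within-group* sums of
squares and products ($s_{xx}$, $s_{yy}$, $s_{xy}$; every deviation taken
from its own group mean), the pooled slope $b = s_{xy}/s_{xx}$, the pooled
$r^2$, and the covariate imbalance statistic

$$f = \frac{n(n-1)\,\Delta\bar x^2}{s_{xx}} = \frac{n}{2}\,d_p^2,$$

which is exactly the $F_{1,2(n-1)}$ statistic comparing the covariate means
($d_p$ is Cohen's standardized mean difference of the covariate).
`ancova_test()` then forms

$$\mathrm{MST} = \frac{n(n-1)\,(\Delta\bar y - b\,\Delta\bar x)^2}{2(n-1)+f},
  \qquad \mathrm{MSE} = \frac{(1-r^2)\,s_{yy}}{2n-3},$$

and $F_{1,2n-3} = \mathrm{MST}/\mathrm{MSE}$, equivalently the squared $t$
statistic of the adjusted difference $\Delta\bar y - b\,\Delta\bar x$ with
standard error
$\sqrt{\mathrm{MSE}\cdot\tfrac2n\,\bigl(1+\tfrac n2 \Delta\bar
x^2/s_{xx}\bigr)}$. The level-$\alpha$ test rejects exactly when the
$1-\alpha$ confidence interval excludes zero; both routes are computed and
the duality is tested property-style. Sums of squares use a two-pass scheme
(means first, then squared deviations) so results are stable across
platforms.

Comparators: `gain_score_test()` is the one-way ANOVA of the per-unit gains
$y - x$ (sensible only when $x$ and $y$ are commensurate, which the package
deliberately does not check), and `anova_y_test()` ignores the covariate
altogether; both have df $(1, 2(n-1))$.

Conventions worth stating: group differences are always group 1 minus
group 2, with group 1 the label seen first in the input file; degenerate 0/0
statistics (no signal, no noise) are reported as $F = 0$, $p = 1$; a perfect
fit with real signal reports $F = \infty$, $p = 0$; unequal group sizes are
rejected outright because every formula above assumes equal $n$.
`imbalance_warning()` implements the advisory rule of thumb ($n > 5$ and
$f > 5$ suggest systematic covariate imbalance) and never alters the
inference.

### A note on printed decimals

On the bundled example data set the exact 95% interval for the adjusted
difference is $[3.6502,\ 19.3160]$. Reports that round intermediate
quantities (slope, standard error, $t$ quantile) to two or three decimals
before combining them arrive at endpoints up to $\pm 0.02$ away, and at a
$p$ value of .011 rather than the exact 0.0105. The package always evaluates
the formulas at full precision and rounds only for display; its tests pin
the exact values and allow the documented $\pm 0.02$ display slack only where
the comparison target is itself a rounded report.

## Exact power

Power rests on three noncentrality parameters, all of the "sum of squared
standardized shifts" form (the square of the corresponding $t$ statistic's
noncentrality — the mainstream noncentral-F parameterization):

* the covariate imbalance $f \sim F_{1,\,2(n-1),\,\lambda}$ with
  $\lambda = \tfrac n2 (\Delta\mu_x/\sigma_x)^2$ (`lambda_ncp()`);
* conditional on $f$, the ANCOVA statistic is
  $F_{1,\,2n-3,\,k(f)}$ with
  $k(f) = n(n-1)\,\bigl(\tfrac{\Delta\mu_y-\beta\Delta\mu_x}{\sigma_e}\bigr)^2
  / \bigl(2(n-1)+f\bigr)$ and
  $\sigma_e^2 = (1-\rho^2)\sigma_y^2$ (`k_of_f()`);
* the gain-score ANOVA is $F_{1,\,2(n-1),\,\theta}$ with
  $\theta = \tfrac n2\bigl(\tfrac{\Delta\mu_y - \Delta\mu_x}{\sigma_{y-x}}\bigr)^2$,
  $\sigma_{y-x}^2 = \sigma_x^2+\sigma_y^2-2\rho\sigma_x\sigma_y$
  (`gain_score_power()`).

With random covariates the ANCOVA statistic therefore follows a **mixture of
noncentral F distributions whose mixing distribution is itself a noncentral
F** (the law of $f$). `unconditional_power()` integrates the conditional
rejection probability over that mixing density; `conditional_power()` is the
fixed-covariate special case. Under the null, $k(f) \equiv 0$ for every $f$,
so the test statistic is central $F_{1,2n-3}$ under *both* frameworks and
the computed power equals $\alpha$ — to quadrature accuracy, about $10^{-9}$.

### Numerical choices

The mixing density with one numerator df behaves like $f^{-1/2}$ at the
origin and is heavy-tailed, so naive quadrature on $f$ is unreliable. The
package substitutes $f = T^2$ where $T$ follows a noncentral
$t_{2(n-1)}(\sqrt\lambda)$ distribution: the integrand in $t$ is smooth on
$(0, \infty)$ (an alternative substitution $u = m/(m+f)$, $m = 2(n-1)$, maps
to a Beta$(m/2, 1/2)$ representation under $\lambda = 0$ but retains an
integrable $(1-u)^{-1/2}$ endpoint singularity, which is why the $t$
representation is used instead). Adaptive quadrature runs at relative
tolerance $10^{-10}$, well inside the $10^{-7}$ absolute target, and any
non-convergence raises an error carrying the integrator's diagnostics rather
than returning a value. Two independent identities guard the scheme:

* null calibration, power $= \alpha$ to $10^{-6}$ over a grid of $n$ and
  $\alpha$;
* the closed form
  $\int_0^\infty \tfrac{n(n-1)}{2(n-1)+f}\, q_{1,2(n-1),0}(f)\,df
  = \tfrac{n(n-1)}{2n-1}$ (the Beta representation above gives it in one
  line), which the unconditional expected treatment mean square
  `expected_mst()` must reproduce to $10^{-6}$.

R's noncentral distribution functions can warn that full precision was not
achieved; the quadrature wrappers suppress these warnings and correctness is
enforced by the two identities instead.

### Designs

`power_request()` encodes the design taxonomy. *Controlled*: the
investigator fixes the covariate values with equal group means, so $f = 0$
in every sample and power is the plain noncentral-F value at $k(0)$.
*Randomized*: $\Delta\mu_x = 0$ (validated), so $\lambda = 0$ but $f$ still
varies sample to sample — power is the mixture value, strictly below the
controlled value. *Observational*: intact groups, $\Delta\mu_x$ free,
$\lambda > 0$, pushing $f$ upward and power further down. *Fixed-x*: an
arbitrary fixed configuration supplying its own $f$. The gain-score and
outcome-only analyses use their exact marginal noncentral-F forms under
every design, since their statistics never involve $f$.

`power_curve()` sweeps one parameter and returns a plain table (tables, not
figures, are the package's output contract), and `solve_sample_size()` finds
the smallest $n$ reaching a target power by bracket doubling plus integer
bisection — valid because every noncentrality above grows with $n$. Grid
minimizers report the grid argmin with ties broken toward the smaller value,
so outputs are deterministic.

### Choosing a covariate: the role of $\rho$

Two opposing effects govern power as $\rho$ grows: the error variance
$\sigma_e^2 = (1-\rho^2)\sigma_y^2$ shrinks (helps), while $\beta = \rho$
(standardized) grows and eats into the adjusted difference
$\Delta\mu_y - \beta\Delta\mu_x$ (hurts when $\Delta\mu_x \neq 0$). With
$\Delta\mu_x = 0$ only the first effect operates and power rises with
$\rho^2$, apart from a small penalty at $\rho \approx 0$ where the adjustment
wastes a degree of freedom and adds noise relative to the plain $t$ test.
With $\Delta\mu_x \neq 0$ the power curve over $\rho$ dips to its minimum at
$\rho = \Delta\mu_x/\Delta\mu_y$ when $|\Delta\mu_y| > |\Delta\mu_x|$
(each mixture component is increasing in $(\Delta\mu_y-\rho\Delta\mu_x)^2 /
(1-\rho^2)$, whose minimizer does not depend on $f$, and $\lambda$ is free of
$\rho$ — so the scalar's minimizer is the power minimizer); when
$|\Delta\mu_y| \le |\Delta\mu_x|$ the curve bottoms out *at the level
$\alpha$* at $\rho = \Delta\mu_y/\Delta\mu_x$, where the null becomes true.
Covariate selection in observational designs should avoid that neighborhood.

### ANCOVA versus gain scores: a quantified edge case

A frequently stated rule holds that with $\sigma_x = \sigma_y$ and
$\Delta\mu_x = 0$ the ANCOVA is more powerful than the gain-score analysis
at every $\rho$. Exact computation shows the rule is *almost* right: at
$n = 10$, $\alpha = .05$ the ANCOVA wins clearly for $\rho \le 0.8$ at all
three effect sizes $\Delta\mu_y \in \{0.5, 1, 1.5\}$, but at $\rho = 0.9$,
where both powers approach 1, the gain score edges ahead by
$5\times10^{-3}$, $9\times10^{-4}$ and $3\times10^{-6}$ respectively: its
noncentrality $\theta = \tfrac n2\Delta\mu_y^2/(2(1-\rho))$ overtakes the
mixture-averaged $k$, and it keeps one more error df. A paired 200,000-
replication simulation confirms the reversal for $\Delta\mu_y = 1$
(difference $\approx 9\times10^{-4}$, several Monte Carlo standard errors
from zero). The package's test suite asserts dominance only on
$\rho \in \{0, \dots, 0.8\}$ and asserts the sub-$10^{-2}$ reversal at 0.9;
the acceptance suite keeps the unqualified claim and documents its failure.
At plotting resolution the curves are indistinguishable near 1, which is
presumably how the blanket rule arose.

## The simulator

`empirical_power()` is the package's internal oracle: every analytic power
value is cross-checked against seeded Monte Carlo rejection rates. Samples
are drawn from the bivariate normal via its Cholesky factor (exact, no
rejection), either fully at random or conditionally on fixed covariate
values. All replications are generated in one vectorized pass from a single
seeded Mersenne–Twister stream, which makes runs bit-reproducible given the
seed — `simulation_config()` requires one — and fast enough that 50,000
replications at $n = 10$ take well under a second. Degenerate replications
($s_{xx} = 0$, impossible under the continuous model but possible with
pathological fixed covariates) are counted and reported, never silently
resampled, since resampling would bias rates. `empirical_f_distribution()`
additionally checks the distributional heart of the method — that $f$ really
follows $F_{1,2(n-1),\lambda}$ — via the Kolmogorov–Smirnov distance.

What the simulator emulates is exactly the model: bivariate normality, equal
covariance matrices, independent units, equal $n$. Real data violate these
in ways the generator deliberately does not reproduce — unequal group
variances, non-normal tails, unequal group sizes, measurement error in $x$
beyond what $\rho$ captures, clustered units. A green Monte-Carlo-versus-
analytic test therefore validates the *mathematics* under the model, not the
model's fit to any particular study.

Test and oracle problem sizes were chosen to make Monte Carlo noise small
relative to the quantities checked while keeping the default suite quick:
50,000 replications for rejection-rate comparisons (3 binomial SEs
$\approx 0.003$ at $\alpha = .05$), 20,000 for distributional checks, $n =
10^4$ for law-of-large-numbers moment checks.

## Limitations

Two groups, one covariate, equal $n$, parallel slopes by construction. No
homogeneity-of-slopes test, no robust or rank-based variants, no missing-data
handling (malformed rows are rejected with their row numbers, not imputed),
and no causal interpretation machinery: the package computes the statistics
and their exact sampling behavior; whether an adjusted difference supports a
causal claim depends on the design, not on the arithmetic.
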