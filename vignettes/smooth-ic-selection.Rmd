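---
title: "Variable selection by smooth information criteria in location-scale regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection by smooth information criteria in location-scale regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicreg)
```

## The model

Many processes in biostatistics and epidemiology are heteroscedastic: the
covariates drive not only the mean of the outcome but also its variability.
`sicreg` fits the distributional ("multiparameter") normal regression

$$ y_i = x_i^T\beta + \varepsilon_i, \qquad
   \varepsilon_i \sim \mathrm{N}\!\left(0,\ \sigma^2_i\right), \qquad
   \sigma^2_i = e^{x_i^T\alpha}, $$

in which the same covariate vector $x_i = (1, x_{1i}, \dots, x_{pi})^T$ is
offered to both the location coefficients $\beta$ and the log-dispersion
coefficients $\alpha$. The log-linear variance keeps $\sigma^2_i$ positive,
and a given covariate may genuinely act on the mean, on the variance, on
both, or on neither — so selection has to happen in both components
simultaneously.

## Selection by a smooth information criterion

Classical information criteria already are penalized likelihoods: with
$\theta = (\beta^T, \alpha^T)^T$,

$$ \mathrm{IC} = -2\ell(\theta)
   + \lambda\left[\|\tilde\beta\|_0 + \|\tilde\alpha\|_0 + 2\right], $$

where $\|\cdot\|_0$ counts non-zero entries of the coefficient vectors
without their intercepts, "+2" accounts for the two intercepts, and
$\lambda = \log n$ (BIC) or $\lambda = 2$ (AIC). Minimizing the BIC over
supports *is* consistent variable selection — but the $L_0$ norm is
non-differentiable, and exhaustive search over $2^{2p}$ supports is
infeasible beyond a handful of covariates.

The package therefore maximizes the *smooth* information criterion obtained
by replacing each indicator with the differentiable surrogate

$$ \phi_\epsilon(x) = \frac{x^2}{x^2 + \epsilon^2} \in [0, 1), \qquad
   \phi_\epsilon(x) \xrightarrow{\ \epsilon \to 0\ } \mathbf 1\{x \neq 0\}, $$

giving the objective

$$ \ell^{\mathrm{SIC}}(\theta) = \ell(\theta) - \frac{\lambda}{2}
   \left[\sum_{j \ge 1}\phi_\epsilon(\beta_j)
       + \sum_{j \ge 1}\phi_\epsilon(\alpha_j) + 2\right]. $$

Because the criterion *is* the objective, no tuning-parameter grid search is
needed — a substantial saving in distributional regression, where a separate
penalty weight per component would otherwise require a two-dimensional grid.

## Optimization: block Newton-Raphson with an $\epsilon$-telescope

Both $\phi_\epsilon$ derivatives are available in closed form, so the
objective is maximized by Newton-Raphson. Following the "RS" idea from
generalized additive models for location/scale, the cross-derivative block
between $\beta$ and $\alpha$ is dropped, leaving two decoupled systems per
iteration,

$$ \left(X^T W_\beta X + \tfrac{\lambda}{2}\Sigma_\beta\right)
   \left(\beta^{(m+1)} - \beta^{(m)}\right)
   = X^T z_\beta - \tfrac{\lambda}{2}\nu_\beta, $$

and the analogous $\alpha$ system, with per-observation weights
$e^{-x_i^T\alpha}$ (location) and
$e^{-x_i^T\alpha}(y_i - x_i^T\beta)^2/2$ (dispersion), and with
$\nu, \Sigma$ holding $\phi'_\epsilon, \phi''_\epsilon$ of the penalized
coefficients (zero in the intercept positions).

A small fixed $\epsilon$ approximates the $L_0$ norm well but sits next to
the discontinuity and makes the optimization unstable; a large $\epsilon$ is
stable but produces no sparsity. The fitting routine therefore *telescopes*
through a geometrically decaying sequence
$\epsilon_t = \epsilon_1 r^{t-1}$, warm-starting each problem from the
previous solution. Null coefficients are squeezed smoothly towards zero —
typical final magnitudes are around $10^{-9}$ — while genuine effects barely
move over the final decades of $\epsilon$.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_start` ($\epsilon_1$) | 10 | first smoothing value; large enough that the first problems are nearly unpenalized and stable |
| `eps_end` ($\epsilon_T$) | 1e-5 | last smoothing value; small enough that $\phi_\epsilon$ is effectively the indicator |
| `n_steps` ($T$) | 100 | telescope length; the endpoints imply decay rate $r = (\epsilon_T/\epsilon_1)^{1/(T-1)} \approx 0.87$. Much smaller $T$ (say 10) degrades selection |
| `penalty_weight` ($\lambda$) | $\log n$ | BIC-type; set 2 for AIC-type |
| `zero_tol` | 1e-8 | post-telescope threshold: final coefficients at or below it are set to exactly 0 |

All are exposed through `make_schedule()` and the fitting functions. A
plausible refinement — tying $\epsilon_T$ to the sample size — lacks an
established rule, so the fixed default is used.

### Numerical choices

* **Initialization.** OLS for $\beta$; $\alpha = (\log s^2, 0, \dots, 0)$
  with the classical residual variance $s^2$ on $n - p$ degrees of freedom.
* **Inner convergence.** Newton iterations at each $\epsilon$ stop when the
  largest absolute coefficient change falls below `1e-8`, capped at 100
  iterations (warm starts mean later steps typically need one or two).
* **Step-halving.** A proposed step is halved (up to 20 times) until the
  objective does not decrease; if no uphill step is found, the parameters
  stay put. The objective is thus monotone across accepted iterations.
* **Indefinite blocks.** $\phi''_\epsilon(x)$ is strongly negative for
  $|x|$ slightly above $\epsilon$, so a penalized block can lose positive
  definiteness; the block is then rebuilt with $|\Sigma|$ (the objective
  check still governs acceptance), and an ill-conditioned block
  (condition number above 1e12) receives a ridge of `1e-8 * mean(diag)`.
* **Variance overflow.** The log-variance linear predictor is clamped to
  $[-30, 30]$ before exponentiation; clips are counted in the result.
* **Thresholding** happens once, after $\epsilon_T$ — never during the
  telescope — and the intercepts are never penalized or thresholded.

## Inference

Standard errors come from the sandwich formula
$\widehat{\mathrm{cov}}(\hat\theta) =
I(\hat\theta)^{-1} I_0(\hat\theta) I(\hat\theta)^{-1}$, where $I$ is the
penalized and $I_0$ the plain observed information (including the
cross-derivative block that the optimizer ignores). It is evaluated at the
raw, pre-threshold estimate with $\epsilon = \epsilon_T$, and reported for
active coefficients. With the penalty off it collapses to $I_0^{-1}$.
Wald intervals use $z = 1.96$ at the 95% level (the conventional rounded
constant; other levels use exact normal quantiles), and prediction intervals
are $x^T\hat\beta \pm 1.96\,e^{x^T\hat\alpha/2}$.

Variable importance is measured by `delta_bic()`: the increase in BIC when
one selected effect is removed from its component and the model is refitted
with the full telescope (removal, not a constrained penalty, because the
question is the cost of dropping the variable). Refits rerun the entire
telescope rather than a one-shot fit at $\epsilon_T$, so the restricted
model enjoys the same stabilized optimization path as the full one.

## What the simulation harness emulates — and what it does not

`table2_design()` + `run_study()` reproduce a deliberately realistic
benchmark: twelve covariates mixing skewed (Exponential(1)), unbalanced
binary (Bernoulli(0.75)), independent standard normal, and an AR(1)-style
correlated Gaussian block (corr $0.8^{|j-k|}$); effects of size 0 / 0.5 / 1
distributed so covariates act on both components, one component only, or
neither. Training predictors are scaled to unit sample SD before fitting
(the standing assumption of equal-footing penalization); the truth is
defined on the generated covariate scale and estimates are mapped back with
the training factors before any comparison, which makes the selection,
coverage and MSE metrics independent of the scaling convention. The holdout
for prediction coverage is a fresh draw of 20% of the training size, scored
with fixed SD strata cutpoints (1, 2.2) — the tertiles of the true
$\sigma_i$ distribution under this design.

A green Monte Carlo test therefore establishes performance under *this*
stated world: moderate dimension (26 parameters), correct normal
specification, smooth covariate effects, independent observations. It says
nothing about gross misspecification (heavy tails, outliers), $p$
approaching $n$, or dependent data; the constant-variance variant
(`fit_spr_sic`) is itself the package's built-in example of what
misspecification does — its prediction intervals over-cover where the true
variance is low and badly under-cover where it is high.

Replicate seeds are derived from the design seed by a fixed integer
recurrence, so studies are exactly reproducible; the test suite runs 200
replicates (not 1000) to stay within its time budget, and its tolerances
are pre-set Monte Carlo bands around the large-replicate reference values.

## Degenerate inputs and edge cases

Rank-deficient designs, constant predictor columns, missing values and
exactly-linear responses (zero residual variance) are rejected with named
errors. A coefficient already below `zero_tol` has `delta_bic = 0` by
definition (warning, not error). If two support patterns tie in BIC, the
smaller support is preferred (parsimony) — relevant only for the exhaustive
reference implementation used in the tests, since the telescope itself never
compares supports explicitly.

## Known limitations

* Only the normal response family is implemented.
* The alternating (backfitting) mean/variance optimization is not offered;
  both blocks are updated in each sweep.
* BIC-drop importance requires one full refit per queried effect, which is
  noticeable with many active coefficients.
* No credible intervals; inference is Wald-type with sandwich SEs, which
  under-cover at small $n$ (visible in the bundled study at $n = 100$).

## A worked example

```{r, eval = FALSE}
set.seed(1)
n <- 1000
df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
df$y <- 1 + df$x1 + rnorm(n, sd = exp((0.5 + 0.8 * df$x2) / 2))

fit <- mpr_sic(y ~ ., df)
summary(fit, delta_bic = TRUE)
plot(fit)                      # telescope paths
predict(fit, type = "prediction")[1:3, ]
```

The Monte Carlo study behind the package's acceptance checks is one call:

```{r, eval = FALSE}
study <- run_study(table2_design(n = 1000, seed = 1),
                   n_replicates = 200, method = "mpr")
print(study)
```
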