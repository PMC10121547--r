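# sicreg — smooth information criterion selection for distributional Gaussian regression

Biostatistical and epidemiological outcomes are often heteroscedastic: the
same covariates that shift the mean of a response also change its spread.
`sicreg` fits the normal *location-scale* (distributional / multiparameter)
regression

    y_i = x_i' beta + e_i,    e_i ~ N(0, sigma_i^2),    sigma_i^2 = exp(x_i' alpha),

and performs variable selection in **both** coefficient vectors at once. It
is aimed at analysts who would otherwise fit a GAMLSS-style model and then
agonize over two penalty tuning parameters: here the selection criterion is
the BIC itself. The non-differentiable L0 penalty of

    IC = -2 l(theta) + lambda [ ||beta~||_0 + ||alpha~||_0 + 2 ],   lambda = log n

is replaced by the smooth surrogate `phi_eps(x) = x^2 / (x^2 + eps^2)`, and
the resulting *smooth information criterion* is maximized directly by a
block Newton–Raphson scheme driven through a geometrically decaying
*epsilon-telescope* (default: 100 steps from 10 down to 1e-5, decay rate
0.87) with warm starts. Truly null coefficients are squeezed to magnitudes
around 1e-9 and thresholded at 1e-8; no tuning-parameter grid search is ever
run. Standard errors use the sandwich formula
`I^-1 I0 I^-1` combining penalized and unpenalized information, and variable
importance is the BIC increase from dropping an effect (`delta_bic()`).

## Worked example

```r
library(sicreg)
set.seed(1)
n  <- 1000
df <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
df$y <- 1 + df$x1 + rnorm(n, sd = exp((0.5 + 0.8 * df$x2) / 2))

fit <- mpr_sic(y ~ ., df)
summary(fit, delta_bic = TRUE)
```

```
Smooth-IC location-scale (MPR) fit: n = 1000, p = 3
log-likelihood -1699.569, SIC 3426.77, BIC 3426.77, df 4

Location (beta):
(intercept)          x1          x2          x3
     1.0088      1.0614      0.0000      0.0000

Dispersion (alpha, log-variance):
(intercept)          x1          x2          x3
     0.5739      0.0000      0.8103      0.0000

Active coefficients (95% Wald intervals):
  component        term index estimate      se  lower  upper delta_bic
   location (intercept)     0   1.0088 0.03558 0.9390 1.0785        NA
   location          x1     1   1.0614 0.03574 0.9913 1.1314     564.2
 dispersion (intercept)     0   0.5739 0.04473 0.4863 0.6616        NA
 dispersion          x2     2   0.8103 0.04487 0.7224 0.8983     321.3
```

The model recovers the generating structure exactly: `x1` acts on the mean
only, `x2` on the log-variance only, `x3` on neither. Estimates sit within
two standard errors of the truth (1 and 0.8), and the BIC-drop column says
removing either selected effect would cost hundreds of BIC units. The
telescope path is visible with `plot(fit)`; `predict(fit, type =
"prediction")` gives 95% prediction intervals whose width adapts to each
observation's fitted variance.

A full Monte Carlo evaluation on the bundled 12-covariate benchmark design
(mixed exponential / binary / normal / correlated-normal covariates, effects
of size 0 / 0.5 / 1 in both components) is one call:

```r
study <- run_study(table2_design(n = 1000, seed = 1),
                   n_replicates = 200, method = "mpr")
print(study)
```

which reports correct/incorrect zero counts, the probability of exact
support recovery, design-weighted MSE, per-coefficient SE/SEE/coverage, and
out-of-sample prediction-interval coverage stratified by the true residual
SD.

## Command line

Thin wrappers over the same functions live in `inst/cli/`:

```sh
Rscript inst/cli/sic-fit.R --data mydata.csv --response y --model mpr --delta-bic --out fit
Rscript inst/cli/sic-simulate.R --n 1000 --replicates 200 --method mpr --out study
```

`sic-fit.R` writes a coefficient report (scaled and original predictor
scales), a JSON model summary and the per-epsilon trace; `sic-simulate.R`
writes tidy study metrics plus a JSON manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the benchmark study from scratch with the installed package (200
replicates at n = 1000) and writes the headline quantity — the mean
estimated dispersion coefficient of the correlated covariate X2 — as JSON.

## Package layout

* `R/penalty.R` — smooth L0 surrogate, derivatives, telescope schedule
* `R/model.R` — log-likelihood, smooth-IC objective, score and information
* `R/fit.R` — initialization, safeguarded Newton steps, telescope driver,
  sandwich covariance, BIC-drop importance
* `R/mpr_sic.R`, `R/inference.R` — formula interface, S3 methods, intervals,
  prediction coverage
* `R/simulation.R` — benchmark design, data generators, Monte Carlo harness
* `R/cli.R`, `inst/cli/` — CSV fitting / simulation entry points
* `vignettes/smooth-ic-selection.Rmd` — model, algorithm and design notes
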