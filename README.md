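# qbill — quantile regression and variable selection for billing aggressiveness

`qbill` analyses **billing aggressiveness** — the ratio of a health-care
provider's average submitted charge to the average payment amount for a
procedure — across the *whole* distribution of providers, not just its
mean. Aggressiveness data are strongly right-skewed and heavy-tailed, and
the covariates that matter for conservative billers (low quantiles) need
not be the ones that matter for potential upcoders (high quantiles). The
package is written for program-integrity analysts and biostatisticians
working with CMS-style provider–procedure claim summaries, and for anyone
who wants an exactly solvable, fully seeded quantile-selection pipeline
with known-truth validation.

## The method

For provider *i* with covariates *x<sub>i</sub>* and aggressiveness
*y<sub>i</sub>*, the linear quantile model is

> y_i = x_i' β* + e_i,  e_i ~ ALD(τ, σ):  f(e) = τ(1−τ) σ⁻¹ exp{−ρ_τ(e)/(2σ)},

where ρ_τ(e) = e(2τ − 2·I(e<0)) is the check loss (factor-2 convention).
Maximum likelihood under the asymmetric Laplace error is check-loss
minimization, and the fit is the conditional τ-quantile of *y*. Fits are
exact linear-programming solutions (interior point plus vertex
polishing). Variable selection at each quantile minimizes

> Σ ρ_τ(y_i − β₀ − x_i'β) + λ n Σ_j |β_j|

over a λ grid in [0.01, 1] (standardized covariates, unpenalized
intercept, coefficients below 0.001 thresholded to zero), choosing λ by
the modified BIC

> BIC(S) = log Σ ρ_τ(y_i − x_iS' β̂_S) + |S| · log(n)/(2n) · C_n,  C_n = log log n,

evaluated at the maximum-likelihood refit β̂_S of each candidate
support. An OLS baseline with Lilliefors residual-normality diagnostics
and Q-Q data documents why mean regression is inadequate, and an xy-pair
bootstrap provides per-quantile confidence bands. A synthetic claims
generator with location-scale structure gives closed-form true quantile
coefficients β(τ) = b + g·F⁻¹(τ) for end-to-end validation.

## Worked example

Simulate an 800-provider mammography-style study with known truth, fit
the 95th percentile, and run BIC selection:

```r
library(qbill)
sim <- simulate_claims_study(800, seed = 7)
dm  <- design_matrix_of(sim$design)

fit_quantreg(scale(dm$X), dm$y, tau = 0.95)
#> Quantile regression fit (tau = 0.95, n = 800, p = 14)
#>   objective (factor-2 check loss): 55.6729
#>   residual signs: 752 below, 15 zero, 33 above
#>               (Intercept)  avg_standardized_payment   gpci_work
#>                  4.471019                 -0.892828    1.006792
#>   ... (remaining 12 coefficients all within 0.06 of zero)

select_lambda(dm$X, dm$y, tau = 0.95)
#> Penalized quantile selection (tau = 0.95, n = 800, p = 14)
#>   lambda_hat = 0.10235 (Cn = 1.9, threshold = 0.001)
#>   selected 3 of 14: avg_standardized_payment, gpci_work, percent_medicaid_eligible

true_beta(sim$truth, 0.95)   # the generator's ground truth, nonzero entries
#>               (Intercept)  avg_standardized_payment                 gpci_work
#>                     4.461                    -0.908                     1.000
#> percent_medicaid_eligible
#>                     1.000
```

The fitted 0.95-quantile coefficients sit within a few hundredths of the
true β(0.95), 752/800 ≈ 94% of residuals lie below the fitted plane (the
LP optimality bound for τ = 0.95), and the selection step recovers
exactly the three truly active covariates. The OLS residual diagnostics
on the same data reject normality decisively:

```r
ols <- fit_ols(dm$X, dm$y)
lilliefors_test(ols$residuals, mc_reps = 2000, seed = 1)
#> Lilliefors D = 0.0787, Monte-Carlo p = 0.0004998
```

A full run — analysis table, OLS table, per-quantile coefficient table
with significance flags, OLS-versus-quantile comparison, and per-quantile
selection — is one call:

```r
cfg <- run_config(mode = "simulate", n = 800, seed = 7, outdir = "run1")
run_pipeline(cfg)   # writes CSV/JSON artifacts with embedded provenance
```

`inst/scripts/qbill.R` wraps the same functions as a command line
(`simulate`, `run --config run.yaml`, `select --table ...`).

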