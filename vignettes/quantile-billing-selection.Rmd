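---
title: "Quantile regression and variable selection for billing aggressiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile regression and variable selection for billing aggressiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbill)
```

## The problem

Fee-for-service claims data summarize, per provider and procedure, the
average charge a provider *submits* and the average amount the payer
actually *allows and pays*. The ratio of the two — **billing
aggressiveness** — is a natural screening variable for upcoding: a
provider charging four times the allowed amount sits in a very different
part of the billing distribution than one charging 1.2 times it.
Aggressiveness distributions are strongly right-skewed and leptokurtic,
and the covariates that matter for conservative billers need not be the
ones that matter for aggressive ones. Mean (OLS) regression answers
neither concern: it models one central tendency with one homoscedastic
error. `qbill` implements the alternative: linear quantile regression
across the whole billing distribution, with an L1-penalized
variable-selection layer driven by a modified BIC.

## Model

For provider $i$ with covariates $x_i \in \mathbb{R}^p$ ($p = 14$ in the
canonical configuration) and aggressiveness $y_i$,

$$y_i = x_i^\top \beta^* + e_i,$$

where $e_i$ follows an asymmetric Laplace distribution (ALD) with density
$f(e) = \tau(1-\tau)\sigma^{-1} \exp\{-\rho_\tau(e)/(2\sigma)\}$ and
$\rho_\tau(e) = e\,(2\tau - 2I(e<0))$ is the check loss in its factor-2
convention. Maximizing the ALD likelihood is identical to minimizing
$\sum_i \rho_\tau(y_i - x_i^\top\beta)$, and the fitted hyperplane is the
conditional $\tau$-quantile of $y$ given $x$. The factor-2 convention
is exactly twice the Koenker convention, so minimizers coincide;
`check_loss()` exposes both and all reported objectives use the factor-2
form.

`fit_quantreg()` solves the problem exactly as a linear program. The LP
is attacked with a Frisch–Newton primal–dual interior-point method on the
bounded-variables dual ($\max y^\top a$ s.t. $X^\top a = X^\top(1-\tau)\mathbf{1}$,
$a \in [0,1]^n$), followed by a *vertex polish*: the optimal fit
interpolates $p+1$ observations, so the rows with the smallest absolute
residuals are completed greedily to a full-rank basis and solved exactly.
The polish makes solutions exact vertices (objective agreement with an
exhaustive basic-solution enumeration to $10^{-15}$ in the test suite)
and, in the penalized variant below, produces *exact* zeros rather than
numerically small coefficients. At the optimum at most $n\tau$ residuals
are strictly negative and at most $n(1-\tau)$ strictly positive — the
finite-sample face of $P(e \le 0 \mid x) = \tau$ — which
`residual_sign_diagnostic()` verifies on every fit.

The default quantile set is $\{0.01, 0.05, 0.25, 0.50, 0.75, 0.95,
0.99\}$: central levels for the bulk, extreme levels for the
conservative and aggressive tails that motivate the analysis.

## Penalized selection

With 14 candidate covariates whose relevance varies by quantile, each
quantile gets its own selection problem. `fit_l1_quantreg()` minimizes

$$\sum_{i=1}^n \rho_\tau(y_i - \beta_0 - x_i^\top\beta) + \lambda n \sum_{j=1}^p |\beta_j|,$$

with the intercept unpenalized and the covariates centered and scaled to
unit standard deviation first (the L1 penalty is scale-sensitive; the
penalty parameterization $\lambda n \sum|\beta_j|$ is stated explicitly
so the default grid is meaningful). The penalized problem is the same LP
with $p$ pseudo-observations — row $e_j$, response 0, level $\tau = 1/2$,
weight $\lambda n$ — because $\lambda n |\beta_j|$ is exactly the
factor-2 median check loss of such a row. One solver therefore serves
both problems, and vertex solutions carry exact zeros.

Selection over $\lambda$ uses the modified BIC

$$\mathrm{BIC}(S) = \log \sum_{i=1}^n \rho_\tau(y_i - x_{iS}^\top \hat\beta_S)
  + |S| \frac{\log n}{2n} C_n,$$

with $|S|$ the number of selected slopes and $C_n \to \infty$. Defaults
and the reasoning behind the open choices:

* **Grid.** 100 log-spaced points in $[0.01, 1]$, configurable. Any
  coefficient whose standardized magnitude falls strictly below 0.001 is
  set to zero (`threshold_support()`); the boundary value is kept, and
  the intercept is never thresholded.
* **$C_n$.** Only "positive and diverging" is prescribed by the theory,
  which leaves the single most consequential constant open. The default
  $C_n = \log\log n$ is the standard choice in the modified-BIC
  variable-selection literature; $\log p$ and user constants are
  available. This choice is deliberately conservative: larger $C_n$
  buys sparsity at the price of power.
* **Loss inside the BIC.** $\hat\beta_S$ in the display above is the
  *maximum-likelihood* (unpenalized) fit on the candidate support, so
  the criterion is evaluated at the MLE refit of each thresholded
  support along the path, with refits cached per distinct support. The
  alternative — plugging in the shrunken penalized estimates — charges
  sparse grid points for their shrinkage bias: in the strong-signal
  validation design it drives exact-support recovery from about 95%
  down to about 30%, because the criterion then prefers small $\lambda$
  where spurious covariates survive. Scoring candidate models at their
  MLE is both the criterion's definition and the variant that works.
* **Ties.** If several $\lambda$ attain the minimal BIC, the largest
  (sparsest model) wins.
* **Reported estimates.** By default the coefficients reported at
  $\hat\lambda$ are the penalized, thresholded estimates mapped back to
  the original covariate scale; `refit = TRUE` reports the unpenalized
  refit on the selected support instead. Both conventions appear in
  applied work and the choice is surfaced rather than hidden.

## OLS baseline and diagnostics

`fit_ols()` (a front end over `stats::lm`) provides the mean-regression
comparison: estimates, classical homoscedastic standard errors (HC1
robust errors behind a flag) and two-sided t-tests. Its residual
diagnostics are the argument for the quantile approach:
`lilliefors_test()` measures the Kolmogorov–Smirnov distance between the
residual ECDF and a normal with *estimated* mean and sd, with the null
distribution obtained by Monte Carlo (each null replicate re-estimates
the parameters, which is what distinguishes Lilliefors from plain KS);
`qq_data()` emits standardized residual order statistics against normal
quantiles at plotting positions $(i - 0.5)/n$. The Monte-Carlo null is
exact for any $n$ and reproducible under a seed; 10⁴ replicates is the
default.

## Uncertainty for quantile coefficients

The interval method behind per-quantile coefficient tables is an
xy-pair bootstrap (`bootstrap_ci()`, default $B = 1000$, percentile
intervals): resampling (x, y) pairs is valid under heteroscedasticity,
which the location-scale structure of quantile-varying coefficients
itself implies, so residual resampling would be self-defeating here.
Rank-inversion and sandwich-covariance intervals are deliberately out of
scope. Significance flags use the proportion-based two-sided p-value
analogue with the conventional three-star scheme; these flags are
bootstrap statements, not asymptotic ones.

## The synthetic claims generator

There is no deposited dataset: the upstream sources are public CMS
extracts whose exact vintages and join conventions are not
reproducible at desk scale. Validation therefore runs on a generator
whose ground truth is known *exactly*:

$$y_i = b_0 + \tilde x_i^\top b + (1 + \tilde x_i^\top g)\,\varepsilon_i,$$

with $\tilde x$ the standardized covariates, $b$ location coefficients,
$g$ heteroscedasticity loadings and $\varepsilon$ iid noise. Under this
location-scale construction the true quantile-coefficient function is
closed-form: $\beta(\tau) = b + g F^{-1}(\tau)$ with intercept
$b_0 + F^{-1}(\tau)$ — every recovery test compares against it
analytically (`true_beta()`). The scale factor is clipped below at 0.05
with a logged count and a 10% budget.

Noise families: ALD (sampled by its exact exponential-mixture
representation — one uniform then one exponential per draw, a documented
order that keeps fixtures stable), shifted lognormal, and scaled
Student t. Defaults: symmetric ALD with $\sigma = 0.1$ (sd ≈ 0.28
against unit-scale standardized signal), a deliberately strong-signal
regime of the kind support-recovery simulation studies use; the
lognormal family defaults ($\mu = 0, \sigma = 1.2$) put the simulated
aggressiveness in the heavily right-skewed regime of real billing data
(sample skewness around 6–9 at the default signal strength).

Covariates mimic a mammography-style extract: negative-binomial service
counts, lognormal payment amounts around \$35 allowed, beta-distributed
state-level proportions, GPCI and HCC indices centered at 1.0, a
provider-type mix dominated by diagnostic radiology, and state-level
variables drawn once per state (30 by default) and shared within state.
The two provider-type aggregate covariates (mean and sd of
aggressiveness by provider type) are *computed from the realized
simulated response*, exactly as the claims feature engineering computes
them, and carry true coefficient zero; this keeps
`emit_raw_files()` → `assemble_design()` an exact inverse and keeps the
self-consistency invariant of the analysis table true by construction.
Per-type response offsets are supported but default to zero, because a
nonzero offset leaks into those realized aggregates and makes them
endogenous — the same leakage caveat the real feature carries (each
provider is included in its own type's aggregate; no leave-one-out).

What the generator deliberately does **not** emulate: the near-perfect
collinearity of real claims (beneficiary counts nearly equal service
counts; standardized and allowed payments correlate above 0.95 in real
extracts). Pairwise correlations are kept moderate (≈ 0.7–0.8) so that
all 14 coefficients remain individually identifiable — the generator's
purpose is ground-truth recovery testing, and a design in which
coefficients are unidentifiable cannot test recovery. It also omits
spatial correlation beyond the shared state effects, fraud labels (the
underlying analysis has none), and the full 89-locality fee-schedule
structure (the locality table is a one-key lookup). Passing tests
demonstrate correctness of the estimators under the stated
location-scale model, not robustness to real-data pathologies.

Aggressiveness is a positive ratio, so the claims-table writer floors
the simulated response at 0.01 with a logged count (zero under default
parameters); estimation studies that need the un-floored response use
`generate_response()` directly.

## Claims ingestion

`load_claims()` validates rows (positive currency fields, beneficiary
count at most service count, known place-of-service and entity enums,
PUF single-letter codes accepted) and counts rejections by reason;
`filter_study_population()` keeps individual-entity facility rows for
the focal procedure and collapses multiple rows per provider by
service-count-weighted means (the source averages are per-service, so
service weighting recovers the pooled mean); `assemble_design()` joins
state covariates and the locality GPCI, drops unmatched rows with a
logged count, and fails when more than half the rows miss the join —
that is a schema problem, not missing data. "Payment amount" in the
aggressiveness denominator is read as the *allowed* amount by default
(the usual convention for this ratio), with the paid and standardized
amounts selectable, because the source phrase is ambiguous among the
three. Proportion columns supplied on a 0–100 scale are detected by
range and rescaled with a warning. Per-type aggregates are computed
within the focal procedure only.

## Numerical choices

* Interior-point: Mehrotra predictor–corrector, duality-gap tolerance
  $10^{-11} n$ on the loss scale, at most 100 iterations, Cholesky with
  a tiny ridge fallback for the $p{\times}p$ normal systems.
* Vertex polish accepts the basic solution only if it does not worsen
  the objective beyond $10^{-9}$ relative — the interior-point iterate
  is kept otherwise.
* When the check-loss minimizer is an interval (intercept-only fits at
  integer $n\tau$), any LP vertex is a valid answer; tests assert the
  objective value, not the non-unique argmin.
* Sample sd uses $n-1$; a provider type with a single member gets
  sd 0 rather than NA so the design matrix stays complete.
* Zero loss at a candidate model maps to BIC $-\infty$ with a warning
  (perfect interpolation wins by fiat); $C_n = \log\log n$ requires
  $n \ge 3$.
* Every random stage (generator, bootstrap, Lilliefors null, pipeline)
  consumes an explicit integer seed and restores the caller's RNG
  state.

## Validation design and problem sizes

The shipped test suite regenerates everything from code: exact-LP
agreement with an exhaustive basic-solution oracle on 200 random small
instances ($n \le 12$, $p \le 2$); penalized objectives against a 2-D
grid search at $p = 1$; residual-sign bounds across the seven-level
quantile set; coefficient recovery on location-scale ALD data at
$n = 5000$, $p = 14$ (mean worst-case error across quantiles about
0.07 on the unit signal scale, 20 seeds); exact-support recovery at
$n = 1000$ with three unit-magnitude actives and unit-sd noise (about
95% over 100 seeds, with at most two false positives in over 90% of
pure-noise runs); Lilliefors null-uniformity (KS over 200 Monte-Carlo
p-values); and byte-identical pipeline determinism. These sizes are the
package's validation design and are restated by `scripts/acceptance.R`,
which recomputes the headline quantities from scratch.

## Known limitations

* Fitted quantile curves are not constrained against crossing; with 14
  covariates and extreme quantiles, crossing can occur in small samples.
  Rearrangement is out of scope.
* The provider-type aggregate covariates leak the focal provider's own
  response into its design row; inference on those two coefficients
  should be read accordingly.
* Bootstrap intervals are percentile intervals; no studentization, no
  rank-inversion.
* The BIC path searches a fixed $\lambda$ grid, not the exact
  breakpoints of the LASSO path; a support attained only between grid
  points can be missed (the default 100-point log grid makes this rare
  in practice).
* The ingestion path is written for analysis-scale extracts (thousands
  of providers for one procedure), not for streaming the full
  multi-million-row national file.
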