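---
title: "Stability selection for zero-inflated volume outcomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability selection for zero-inflated volume outcomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zinbstab)
```

## The problem

White matter hyperintensity (WMH) volume in population cohorts has two
awkward statistical features: a large point mass at zero (many participants
carry no measurable lesion load) and a strongly right-skewed, overdispersed
positive part. On top of that, candidate risk-factor panels are wide
relative to the sample (e.g. ~90 covariates against a few hundred
participants) and internally collinear — blood-pressure measures correlate
with each other and with hypertension categories, glycemic measures with
diabetes status, and so on. Ordinary regression cannot select among such
panels; `zinbstab` implements the combination that can: a zero-inflated
negative binomial (ZINB) outcome model, elastic-net shrinkage for selection
under collinearity, and resampling-based selection frequencies as the
importance measure.

## The model

For participant $i$ with covariate row $x_i$ (continuous covariates
standardized to mean 0, SD 1), WMH volume in mm$^3$ is modelled as

$$
Y_i \sim \begin{cases}
0 & \text{with probability } \pi_i \\
\mathrm{NB}(\mu_i, \theta) & \text{with probability } 1 - \pi_i,
\end{cases}
\qquad
\log \mu_i = \beta_0 + x_i^\top \beta, \quad
\mathrm{logit}\, \pi_i = \gamma_0 + x_i^\top \gamma .
$$

The NB2 count part has variance $\mu + \mu^2/\theta$; exponentiated
count-part coefficients are incidence rate ratios for expected volume. Both
coefficient vectors share the covariate set and both are penalized; the
intercepts and $\theta$ are not. The fitted objective is

$$
J(\beta_0,\beta,\gamma_0,\gamma,\theta)
 = -\tfrac1n \,\ell_{\mathrm{ZINB}}
 + \lambda \sum_j \Big[\alpha\,(|\beta_j|+|\gamma_j|)
 + \tfrac{1-\alpha}{2}\,(\beta_j^2+\gamma_j^2)\Big],
$$

with the mean (not summed) log-likelihood so that $\lambda_{\max}$ is stable
in $n$. $\alpha \in (0,1]$ blends ridge ($\alpha \to 0$) and lasso
($\alpha = 1$).

## Fitting: EM with coordinate descent

The zero mixture is handled by EM. The E-step computes posterior
structural-zero weights for the observed zeros,
$z_i = \pi_i / [\pi_i + (1-\pi_i)\,f_{\mathrm{NB}}(0;\mu_i,\theta)]$
(log-sum-exp throughout). The M-step solves two penalized weighted GLMs by
IRLS whose inner weighted least-squares problems go through a C++
cyclic coordinate-descent kernel with soft-thresholding — inactive
coefficients are *exact* zeros, which is what makes selection-frequency
counting well defined without a tolerance. $\theta$ is updated by Brent
search on $\log\theta \in [\log 10^{-3}, \log 10^{6}]$.

Because one IRLS pass is only a quadratic approximation, each EM iteration
is guarded: if the penalized objective would increase, the step is halved
back toward the previous iterate (on $\beta,\gamma$, intercepts and
$\log\theta$) and, failing that, the iteration stops at the previous
iterate. The recorded objective trace is therefore non-increasing by
construction, and the test suite asserts it at $10^{-10}$ on every recorded
fit. Convergence is declared at a relative objective change below `em_tol`
($10^{-6}$ by default, at most 200 EM iterations; coordinate descent runs to
a $10^{-8}$ coefficient-change tolerance, at most 1000 sweeps).

Default initialization is the tightly converged intercept-only fit. That
choice matters for the $\lambda_{\max}$ property: at the null fixed point the
Karush-Kuhn-Tucker condition $\max_j |s_j|/\alpha \le \lambda$ (score $s_j$
of either part, evaluated with the null fit's E-step weights) guarantees the
penalized EM never leaves the null model, so `compute_lambda_max()` can
return the KKT bound directly (nudged by a relative $10^{-8}$ off the
floating-point knife edge, and certified by one refit). A 20-step bisection
refinement against actual refits is available (`refine = TRUE`) and is
cross-checked in the tests against a 200-point grid scan; the pipeline uses
the KKT value because per-split bisection would cost ~20 extra fits per
training set for an identical answer.

## Tuning and the stability run

Per training set, $\lambda$ is tuned by ten-fold cross-validation over two
log-spaced paths capped at $0.5\,\lambda_{\max}$ and $0.1\,\lambda_{\max}$
(both descending to $10^{-3}\lambda_{\max}$, 20 points each by default; the
scaled-down runs in the tests use 8-10 points). The CV criterion is held-out
log-likelihood — the natural deviance criterion for a count mixture, and it
also exercises the zero part, which test RMSE barely sees. The default
selection rule is the one-standard-error rule (largest $\lambda$ within one
SE of the best mean held-out log-likelihood); `rule = "min"` gives the raw
maximiser. The 1-SE default reflects that CV here tunes a *selection*
procedure, where the raw maximiser is known to over-select. Note one
structural consequence of the caps: even the sparsest reachable model sits
at $\lambda = 0.5\,\lambda_{\max}$, so on pure-noise data every column whose
score exceeds half the maximal noise score is retained; with wide panels a
handful of noise variables in any single fit is expected, which is exactly
why importance is judged by selection *frequency* across splits rather than
by any single active set.

The stability run draws `n_splits` random 90/10 train/test splits. For each
split and each $\alpha$ on the grid (default
$\{0.01, 0.1, \dots, 0.9, 1\}$, which contains both of the winning values in
the motivating analyses), continuous covariates are re-standardized with
training-row statistics only (no leakage into the held-out 10%; passing an
already-standardized design instead makes this step a no-op and reproduces
the once-on-the-full-sample convention, which is the other defensible
reading of the procedure), $\lambda$
is CV-tuned, the model is refitted on the full training part, and the
count-part active set, test RMSE and train AIC are recorded. A variable's
selection frequency is the fraction of splits with a nonzero count-part
coefficient; its reported effect is the mean of the fitted coefficient over
the splits where it was selected. The best $\alpha$ minimises mean test RMSE
with mean train AIC as tie-breaker. AIC uses the lasso degrees-of-freedom
convention (number of nonzero coefficients + intercepts + $\theta$).

Ranking is by descending frequency, ties broken by larger mean
$|\hat\beta|$, then variable name. The null comparison refits on the whole
sample and reports RMSE, AIC and a likelihood-ratio test against the
intercept-only model (which predicts the constant sample mean — exact at the
ZINB null MLE); the LRT degrees of freedom are the difference in the
lasso-df counts. With penalized selection the $\chi^2$ reference is
informal; the calibration simulation in the tests therefore uses an
unpenalized two-covariate configuration, where the test is exact
asymptotically.

## Replication in a second cohort

The top-$k$ ($k = 10$ by default) discovery variables are carried into the
second cohort twice: an *unpenalized* plain NB regression on exactly those
design columns against the null model on the whole sample (the second
cohort's outcome, measured differently, has few zeros, so plain NB is the
default there; ZINB is available by flag), and an elastic-net stability
re-ranking over that cohort's own splits. Statuses: `replicated` if the
replication frequency reaches the threshold (0.5 by default — the discovery
procedure itself uses no cut-off, so this is an explicit artifact decision,
config-exposed) with matching effect sign; `direction_discordant` if the
frequency is reached with the sign flipped; `not_replicated` otherwise.
Variables absent from the second panel must be mapped explicitly (e.g. a
"widowed" indicator to "living alone"); mapped variables get status
`substituted` with the rule's outcome on the substitute reported alongside.
Mappings are never inferred.

## The synthetic cohort generator

No participant-level data from the motivating cohorts is available, so the
generator emulates their structure with full ground truth. Covariates are
declared per column (continuous with mean/SD, binary with prevalence,
categorical with level probabilities) and grouped into correlation blocks: a
block shares a latent standard-normal factor with loading
$\sqrt{\rho}$, giving equicorrelation $\rho$ on the latent scale before the
marginal transform (affine for continuous, quantile thresholds for
binary/categorical). Outcomes follow the ZINB model above; continuous
covariates enter the truth standardized, so declared effects are per-SD.
The structural-zero part defaults to an intercept plus an age effect —
the zero-part design is an explicit, configurable choice of the generator.

Two ready-made scenarios fix the study conditions: `kora_like` (400
participants, 370 after the packaged 12/2/16 exclusion flow; 90 variables in
realistic blocks; ten nonzero count-part effects with $|\beta| \in
[0.1, 0.5]$ per SD; $\theta = 0.8$) and `ship_like` (854 participants, 34
variables, shared effects where the panels overlap, $\theta = 0.6$).
Marginals follow the published descriptive table; dispersions were chosen to
reproduce a strongly right-skewed outcome with median far below the mean.
What the generator does *not* emulate: segmentation-method differences
between cohorts (the motivating samples were measured with different MRI
pipelines, which the generator represents only through different intercepts
and dispersions), non-Gaussian dependence within blocks, missing-data
mechanisms beyond flagged missingness, and measurement error in covariates.
Passing tests therefore demonstrate correctness of the *procedure* under the
assumed data-generating model, not field performance on real cohorts.

## Numerical choices and degenerate inputs

- Linear predictors are capped at $\pm 30$ before exponentiation.
- Standardization uses the population SD (divide by $n$): "SD = 1" is
  otherwise ambiguous, and the population form keeps two-point examples
  exact. Zero-variance continuous training columns are an error.
- Volumes are rounded half-up to integer mm$^3$ on ingest; the count model
  requires integers and published volumes are whole mm$^3$.
- Dummy coding takes the most frequent level as reference (ties: codebook
  order), so the rarer, clinically marked levels are the selectable
  predictors.
- Exclusion accounting is sequential (first matching flag in the stated
  order), matching participant flow diagrams when flags overlap; the
  surviving set is order-invariant.
- All-zero outcomes are a validation error for model fitting; CV folds with
  all-zero training outcomes under the NB family are skipped with a warning,
  and only an entirely skipped CV errors.
- `nb_log_pmf` switches to an exact product-log sum for the
  $\Gamma$-function ratio when $\theta > 10^6$, where the `lgamma`
  difference cancels catastrophically.
- Every random stage derives its seed from the single master seed and a
  stage label; per-split CV streams hash the split's test indices, so
  results are invariant to the order in which splits are processed (the
  property that makes parallel and serial execution equivalent). Runs are
  byte-identical given identical configurations.

## Scaled problem sizes

The test and acceptance runs use scaled-down versions of the full design —
100 splits instead of 1000, paths of 8-10 $\lambda$ values instead of 20,
single-$\alpha$ grids where the property under test does not involve the
grid, and a power/noise configuration of one strong effect ($\beta = 0.8$
per SD, $\theta = 2$, structural-zero probability 0.25) among 20 nulls at
$n = 400$. These sizes are the package's registered simulation conditions
for its own checks; the full-size run is a matter of `n_splits = 1000`,
`n_lambda = 20` and the default grid.

## Known limitations

- The penalized ZINB objective is nonconvex; the EM finds a descent path,
  not a certified global optimum (the brute-force oracle in the tests checks
  agreement on small instances).
- Selection frequencies carry no formal error control; they are descriptive
  importance measures, as in the motivating analysis.
- The LRT after penalized selection is an informal fit diagnostic, not a
  calibrated test.
- No imputation: participants with missing covariates are excluded, as in
  the motivating studies.
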