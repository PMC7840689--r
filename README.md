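# zinbstab

Elastic-net **z**ero-**i**nflated **n**egative **b**inomial regression with
**stab**ility selection, for epidemiologists asking which of a wide,
collinear panel of candidate risk factors is associated with a
zero-inflated, overdispersed outcome — the motivating case being cerebral
white matter hyperintensity (WMH) volume in mm³ in population MRI cohorts.

## What it does

WMH volume has a point mass at zero (participants without lesions) and a
heavily right-skewed positive part. `zinbstab` models it as

- a **ZINB mixture**: structural zero with probability
  `π(x) = plogis(γ₀ + xᵀγ)`, otherwise NB with mean
  `μ(x) = exp(β₀ + xᵀβ)` and dispersion `θ` (variance `μ + μ²/θ`);
- an **elastic-net penalty** `λ Σⱼ [α|bⱼ| + (1−α)/2 bⱼ²]` on both
  coefficient vectors (intercepts and `θ` free), fitted by EM with a C++
  coordinate-descent kernel that produces exact zeros;
- **λ tuned by ten-fold cross-validation** on log-spaced paths capped at
  0.5 and 0.1 of `λ_max` (the smallest penalty shrinking everything to
  zero);
- **stability selection**: repeated random 90/10 train/test splits; a
  variable's importance is its selection frequency — the fraction of splits
  in which its count-part coefficient is nonzero — with effect sizes
  reported as the mean coefficient over the splits where it was selected
  (exponentiate for incidence rate ratios);
- **null comparison** (RMSE on held-out data, AIC on training data,
  likelihood-ratio test against the intercept-only model) and
- **replication**: the top-k discovery variables re-examined in a second
  cohort by a whole-sample NB fit vs null plus a split-based re-ranking,
  with replicated / direction-discordant / not-replicated statuses.

A synthetic-cohort generator (correlated mixed-type covariate blocks, ZINB
outcome, full ground truth) emulates the structure of the two motivating
cohorts and drives all tests.

## Worked example

```r
library(zinbstab)

# simulate a discovery-like cohort and apply the exclusion flow
fx  <- make_kora_like_fixture(seed = 1)      # 400 participants, flagged
res <- apply_exclusions(fx, c("insufficient_quality", "other_aetiology",
                              "missing_covariates"))
res$report
#> insufficient_quality      other_aetiology   missing_covariates
#>                   12                    2                   16
nrow(res$cohort)
#> [1] 370

# stability selection on a small synthetic panel (scaled down: 1 strong
# effect of 0.8 per SD among 20 nulls, 100 splits, alpha = 0.8)
set.seed(230)
X <- matrix(rnorm(400 * 21), 400, 21,
            dimnames = list(NULL, c("strong", sprintf("null%02d", 1:20))))
y <- ifelse(runif(400) < 0.25, 0,
            rnbinom(400, size = 2, mu = exp(4 + 0.8 * X[, "strong"])))
d <- structure(list(X = X, y = y,
       col_info = data.frame(column = colnames(X), variable = colnames(X),
                             level = "continuous", type = "continuous",
                             standardized = FALSE, train_mean = NA_real_,
                             train_sd = NA_real_)), class = "zinb_design")
stab <- run_stability(design = d, scheme = make_splits(400, 100, 0.1, 231),
                      alpha_grid = 0.8, family = "zinb", n_lambda = 10)
head(rank_variables(stab, 3))
#>   variable frequency mean_beta_selected
#> 1   strong         1          0.4690141
#> 2   null01         0                 NA
#> 3   null02         0                 NA
```

The strong effect is selected in all 100 splits; under the default
one-standard-error tuning rule none of the 20 noise variables is ever
selected. The mean selected coefficient (0.47) is shrunken relative to the
generating 0.8 per SD, as expected for a penalized estimate — refit
unpenalized on the active set (or see `compare_to_null()`) for unshrunken
effects. `compare_to_null()` then reports the tuned
model's RMSE/AIC against the intercept-only model plus the LRT, and
`replicate_top_k()` carries the ranking into a second cohort.

A thin command-line wrapper with `simulate`, `stability`, `replicate` and
`report` subcommands lives at `inst/cli/zinbstab.R`.

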