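# ordinalBVS

Penalized Bayesian cumulative-logit (proportional-odds) regression with
variable selection for high-dimensional ordinal responses — the p >> n
setting of relating gene expression to an ordered phenotype such as an
acute myeloid leukemia prognostic risk group (favorable < intermediate <
adverse). It is aimed at biostatisticians who want feature identification
backed by a hypothesis test (Bayes factors) rather than by the nonzero set
of a penalized point estimate.

## Models

For ordered response $Y_i \in \{1,\dots,K\}$ and standardized features
$x_i$:

$$\log\frac{P(Y_i \le k \mid x_i)}{P(Y_i > k \mid x_i)} = \alpha_k - \beta'x_i,
\qquad \alpha_1 < \cdots < \alpha_{K-1},$$

with four coefficient priors:

| model | prior on $\beta_j$ |
|---|---|
| I — Bayesian LASSO | $\mathrm{DE}(0, 1/\lambda)$, $\lambda \sim \mathrm{Gamma}(a,b)$ |
| II — spike-and-slab normal | $(1-\gamma_j) N(0,\sigma_0^2) + \gamma_j N(0,\sigma_1^2)$ |
| III — spike-and-slab LASSO | $(1-\gamma_j)\mathrm{DE}(0,1/\lambda_0) + \gamma_j \mathrm{DE}(0,1/\lambda)$ |
| IV — inclusion-indicator regression | predictor is $\sum_j \gamma_j\beta_j x_{ij}$; $\beta_j \sim \mathrm{DE}(0,1/\lambda)$ |

with $\gamma_j \sim \mathrm{Bernoulli}(\pi_j)$ and $\pi_j = t$ fixed or
$\pi_j \sim \mathrm{Beta}(c,d)$. Sampling is slice-within-Gibbs (C++), and
features are identified by the Bayes factor
$B_{10} = \text{posterior odds}/\text{prior odds}$ for either
$H_0\!:\gamma_j = 0$ (Models II–IV) or the interval null
$H_0\!:|\beta_j| \le \epsilon$ (all models; $|\gamma_j\beta_j|$ for IV),
rejecting when $B_{10} > 5$. Equal-tailed and HPD credible intervals,
Gelman–Rubin diagnostics, SD-quantile filtering, a synthetic-data
generator, and a command-line front end (`inst/cli/ordinalBVS.R`) round out
the toolkit. See the vignette in `vignettes/` for the full methods account.

## Worked example

```r
library(ordinalBVS)

sim <- simulateOrdinal(n = 200, p = 20, supportSize = 3, effect = 1.5,
                       seed = 42)
sim$data
#> OrdinalDataset: 200 samples x 20 features, 3 ordered categories
#>   category counts: 1=70, 2=69, 3=61

fit <- fitBayesOrdinal(sim$data, priorSpec("IV", t = 0.05),
                       mcmcControl(nChains = 3, nBurnin = 500, nAdapt = 200,
                                   thin = 1, nSavedTotal = 6000, seed = 1))

bf <- bayesFactors(fit, bfTest("gamma"))
selectFeatures(bf)
#>   feature_id prior_odds posterior_odds     bf rejected
#> 1    feat001     0.0526          12001 228019     TRUE
#> 2    feat002     0.0526          12001 228019     TRUE
#> 3    feat003     0.0526          12001 228019     TRUE

convergenceReport(fit)
#> ConvergenceReport: 3 chains x 2000 iterations, cutoff 1.1
#>   max PSRF 1.0042 (lambda)
#>   no parameters above the cutoff

scoreSelection(selectFeatures(bf)$feature_id, sim$truth,
               featureIds = featureIds(fit))
#> $sensitivity  [1] 1
#> $fdr          [1] 0
#> $n_selected   [1] 3
```

The three planted features (coefficients ±1.5 on the standardized scale)
are recovered exactly: their indicator chains sit at 1 in essentially every
saved draw, so the continuity-corrected posterior odds are 12001 against a
prior odds of 0.05/0.95 ≈ 0.0526, giving Bayes factors far above the
rejection threshold of 5. `prior_odds` comes from the closed-form marginal
inclusion odds; `posterior_odds` is the corrected draw-count ratio pooled
across chains.

Real expression matrices should first pass through
`filterBySdQuantile()` and `standardizeFeatures()` (or
`ordinalDataset(..., standardize = TRUE)`); the model defaults assume
unit-variance features.

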