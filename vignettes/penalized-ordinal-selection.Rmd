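---
title: "Penalized Bayesian cumulative-logit models for high-dimensional ordinal responses"
author: "ordinalBVS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized Bayesian cumulative-logit models for high-dimensional ordinal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Many genomic phenotypes are ordered but not numeric: prognostic risk groups
in acute myeloid leukemia (favorable < intermediate < adverse), tumor grades,
severity scores. Relating gene expression to such a phenotype means fitting
an ordinal regression with p features for n samples where p >> n, and —
because the point of the exercise is gene discovery — doing variable
selection with an actual hypothesis test rather than "whatever is nonzero at
the penalty the cross-validation picked". ordinalBVS implements four
penalized Bayesian proportional-odds models whose posterior output supports
Bayes-factor tests per feature.

## Model

For ordered response $Y_i \in \{1,\dots,K\}$ and standardized features
$x_i$, the cumulative-logit (proportional-odds) model is

$$\log\frac{P(Y_i \le k\,|\,x_i)}{P(Y_i > k\,|\,x_i)} = \alpha_k - \beta'x_i,
\qquad k = 1,\dots,K-1,$$

with strictly increasing thresholds $\alpha_1 < \cdots < \alpha_{K-1}$.
Equivalently $Y_i = k$ when a latent variable $Z_i = \beta'x_i + \epsilon_i$
with standard-logistic noise falls in $(\alpha_{k-1}, \alpha_k]$. The sign
convention is $\alpha_k - \beta'x$ throughout: larger $\beta'x$ pushes mass
toward higher categories. Proportional odds is assumed, not tested.

Four coefficient priors are offered:

* **Model I (Bayesian LASSO):** $\beta_j\,|\,\lambda \sim \mathrm{DE}(0, 1/\lambda)$,
  $\lambda \sim \mathrm{Gamma}(a, b)$. The double-exponential prior's
  posterior mode is the LASSO; the Gamma hyperprior removes the need to pick
  a penalty value.
* **Model II (spike-and-slab normal):**
  $\beta_j\,|\,\gamma_j \sim (1-\gamma_j)\,N(0, \sigma_0^2) + \gamma_j\,N(0, \sigma_1^2)$
  with inclusion indicator $\gamma_j \sim \mathrm{Bernoulli}(\pi_j)$.
* **Model III (spike-and-slab LASSO):**
  $\beta_j\,|\,\lambda,\gamma_j \sim (1-\gamma_j)\,\mathrm{DE}(0, 1/\lambda_0) + \gamma_j\,\mathrm{DE}(0, 1/\lambda)$,
  spike rate $\lambda_0$ fixed and large, slab rate Gamma-mixed.
* **Model IV (inclusion-indicator regression):** the predictor itself is
  $\sum_j \gamma_j \beta_j x_{ij}$, so $\gamma_j = 0$ removes the feature
  from the model; $\beta_j\,|\,\lambda \sim \mathrm{DE}(0, 1/\lambda)$ for
  every $j$.

In Models II and III the indicator only relabels the prior mixture — the
coefficient stays in the likelihood either way; only Model IV gates the
predictor. This asymmetry is deliberate and tested. $\pi_j$ is either a
fixed constant $t$ or feature-specific $\mathrm{Beta}(c, d)$.

## Defaults and what they mean

All defaults assume **standardized features** (columns mean 0, sample SD 1;
enforced by the data container), so coefficients are on a per-SD scale.

| parameter | default | meaning |
|---|---|---|
| $a, b$ | 0.1, 0.1 | diffuse Gamma on the LASSO rate; posterior insensitive unless both are large |
| $\sigma^2_\alpha$ | 10 | threshold prior variance — wide enough to cover the latent-variable range |
| $\sigma_0^2, \sigma_1^2$ | 0.01, 10 | Model II spike (essentially zero per-SD effect) and slab |
| $\lambda_0$ | 20 | Model III spike rate: prior SD of a spike coefficient is $\sqrt2/20 \approx 0.07$ |
| $t$ | 0.5 / 0.05 | uninformative vs informative guess of the fraction of relevant features |
| $c, d$ | (1, 19) or (0.01, 0.19) | Beta hyperpriors with mean 0.05, the second much more variable |
| MCMC | 3 chains, 5000 burn-in, 5000 adapt, thin 3, 9999 saved | the fitting protocol used for the AML-scale analysis |

The threshold prior is written per-$k$ internally ($\sigma^2_{\alpha_k}$, a
vector argument), defaulting to a shared 10. The 9999 saved draws are
interpreted as a **total across chains** (3333 per chain under the default
three); this is a convention choice. Chains are pooled after discarding
burn-in and adaptation for all selection quantities; per-chain summaries
remain available to the diagnostics.

## Sampling

The posterior is explored by slice sampling within Gibbs: univariate
stepping-out/shrinkage slice updates for each $\alpha_k$ (restricted to
$(\alpha_{k-1}, \alpha_{k+1})$, so ordering violations are impossible by
construction) and each $\beta_j$, and conjugate draws for
$\lambda \sim \mathrm{Gamma}(a + m,\, b + S)$ (with $m = p$, $S = \sum|\beta_j|$
for Models I/IV and the slab-only sums for Model III),
$\gamma_j$ (Bernoulli from the spike/slab density ratio, times the
likelihood ratio in Model IV), and
$\pi_j \sim \mathrm{Beta}(c + \gamma_j,\, d + 1 - \gamma_j)$. In Model IV a
coefficient whose indicator is 0 drops out of the likelihood and is
refreshed exactly from its conditional DE prior.

Slice sampling is tuning-free up to a step width. Widths adapt during the
adaptation phase (toward twice the typical accepted move) and then freeze;
in addition the width for $\beta_j$ is floored at twice the conditional
prior scale ($2/\lambda$ for DE priors, $2\sigma$ for normal ones). That
floor matters: under a diffuse Gamma the conditional scale $1/\lambda$ can
be orders of magnitude larger than any adapted width, and a fixed-width
sampler mixes arbitrarily slowly through such states. A slice width may
depend on other components of the state without affecting the invariant
distribution.

Initialization: thresholds start at the empirical logit cumulative
frequencies with seed-derived per-chain jitter (overdispersed starts for the
Gelman–Rubin diagnostic); $\beta = 0$; $\gamma$ drawn from its prior;
$\lambda = a/b$. A fit is a deterministic function of (data, prior, control):
identical seeds give bit-identical draws.

The logistic CDF and all category probabilities are computed in
branch-stable form (no overflow for $|\alpha_k - \eta| > 30$); interior
category probabilities use
$\log(F(b) - F(a)) = \log F(b) + \log F(-a) + \log(1 - e^{a-b})$.

## Feature identification

Two Bayes-factor tests are provided, both with
$B_{10} = \text{posterior odds} / \text{prior odds}$ and the strict rule
"reject $H_0$ when $B_{10} > 5$":

* **Indicator test** (Models II–IV): $H_0\!: \gamma_j = 0$ vs
  $H_1\!: \gamma_j = 1$. Prior odds are $t/(1-t)$, or $c/d$ under the Beta
  hyperprior (the marginal $P(\gamma_j = 1)$ is $c/(c+d)$).
* **Interval-null test**: $H_0\!: |\beta_j| \le \epsilon$ vs
  $H_1\!: |\beta_j| > \epsilon$ with $\epsilon = 0.10$ by default — a
  continuous prior puts no mass at exactly zero, so a point null is not
  testable. Model IV tests $|\gamma_j\beta_j|$ instead, since its $\beta_j$
  is meaningless while excluded. Closed-form prior tail masses: Model I
  $(b/(b+\epsilon))^a$; Model II
  $(1-\bar\pi)\,2\Phi(-\epsilon/\sigma_0) + \bar\pi\,2\Phi(-\epsilon/\sigma_1)$;
  Model III $(1-\bar\pi)e^{-\lambda_0\epsilon} + \bar\pi(b/(b+\epsilon))^a$;
  Model IV $\bar\pi\,(b/(b+\epsilon))^a$. These re-derivations are validated
  against Monte-Carlo prior sampling in the test suite rather than assumed.

Posterior odds are estimated by counting pooled draws in $H_1$, with a
continuity correction $(m + \tfrac12)/(N - m + \tfrac12)$ so an indicator
chain stuck at 0 or 1 yields a finite Bayes factor; the raw count ratio is
available via `correction = FALSE`. Model I supports only the interval test
(it has no indicator). 95% equal-tailed and HPD credible intervals are also
provided for interval-based selection; the HPD implementation assumes a
unimodal posterior (shortest contiguous window of sorted draws).

$\epsilon$ is an arbitrary analyst choice with no data-driven guidance,
which is why the indicator test is the recommended route.

## Synthetic data and what passing tests mean

`simulateOrdinal()` generates data through exactly the latent mechanism the
models assume: standardized Gaussian features with optional exchangeable
correlation $\rho$, a sparse coefficient vector with alternating-sign
effects (so selection isn't confounded with one direction), logistic noise,
threshold binning. For $K = 3$ the default thresholds reproduce a
97:259:97 category mix — the composition typical of cytogenetic risk groups
in an AML cohort; other $K$ get equal-probability cuts. The generator
refuses (after logged retries) to emit a response missing a category.

It deliberately does **not** emulate probe-level measurement noise, batch
effects, heavy-tailed expression distributions, or realistic gene–gene
covariance. Recovery results on these data therefore demonstrate that the
samplers and tests work when the model is true — a correctness statement,
not a claim about performance on real expression matrices, where
multicollinearity is known to flip coefficient signs and widen credible
intervals past zero.

## Validation design

Three independent oracles back the test suite:

* **Dense-grid integration** (n = 30, p = 2, K = 3): posterior moments for
  every variant computed by brute force on a sinh-spaced coefficient grid
  (the near-zero spike of the heavy-tailed priors needs ~0.004 resolution
  while the tails extend past ±8; uniform grids of feasible size are
  visibly biased). Indicator configurations are summed over explicitly for
  Model IV, with excluded coefficients integrated out analytically. Sampler
  moments must match within 3 Monte-Carlo standard errors plus a 0.02 grid
  allowance. For Model IV the compared quantities are $\alpha$, $E[\gamma_j]$
  and moments of $\gamma_j\beta_j$: the bare $\beta_j$ marginal mixes in the
  pure DE-Gamma prior, whose second moment is infinite at $a = 0.1$, so its
  sample mean/SD is not a usable target.
* **Successive-conditional (joint-distribution) simulation**: draw
  parameters from the prior, data given parameters, then alternate one Gibbs
  sweep with a data refresh; the parameter marginals must stay at the prior.
  Run for Models I and IV at 20,000 transitions, thinned by 10 before a
  two-sample KS test against independent prior draws (KS assumes
  independence). The validation uses $a = b = 2$: with the default
  $a = b = 0.1$ the marginal coefficient prior has $|b|^{-1.1}$ tails
  (infinite mean) and the refreshed data become degenerate during tail
  excursions, leaving autocorrelation that fails KS for reasons unrelated to
  kernel correctness; at $a = b = 2$ the identical code paths mix well and
  the test is sharper against genuine bias.
* **Monte-Carlo prior sampling** (10^6 draws) for every closed-form prior
  odds / tail probability, within 3 binomial standard errors.

Recovery is exercised at n = 300, p = 50, five true coefficients of
$\pm 1.5$, five seeds, with a reduced budget of 3 chains × 2000 saved draws
(burn-in 500, adaptation 200) — sizes chosen so the full suite stays
comfortably re-runnable on one core. One caveat discovered at these
conditions: with effects this strong both the informative ($\pi = 0.05$) and
uninformative ($\pi = 0.5$) priors select essentially the whole support, so
the expected ordering "informative finds at least as many features" is
decided by borderline false positives and can invert by one feature in a
given seed set. The ordering is a property of weak-signal regimes; the
corresponding check reports per-seed counts to make this visible.

## Other numerical choices

* SD-quantile filtering keeps columns with SD **at or above** the
  linear-interpolation quantile of column SDs — ties at the threshold are
  kept, so a maximal-variance feature is never silently dropped; sample SDs
  use the $n-1$ denominator.
* Standardization errors out on constant columns, naming the feature.
* Classical (non-split, non-rank-normalized) Gelman–Rubin $\hat R$, matching
  the era of the protocol it accompanies; a split variant sits behind
  `split = TRUE`. Indicator chains are excluded from $\hat R$ (binary chains
  make it ill-behaved) and summarized by per-chain means instead. The 1.1
  flag cutoff is configurable, not canonical.
* Degenerate $\hat R$ conventions: all chains constant and equal → 1;
  constant but different → Inf.
* `lambda` draws are floored at 1e-300 to keep conditional scales finite in
  pathological states.

## Limitations

Proportional odds is assumed and untested; non-proportional and stereotype
logit models, probit links, and frequentist FDR control are out of scope.
HPD intervals assume unimodality. The samplers are serial; the AML-scale
protocol (thousands of features, 20k iterations) is a multi-hour run, as
expected for this model class.
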