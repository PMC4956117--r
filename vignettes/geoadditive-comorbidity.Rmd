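---
title: "Geo-additive multinomial modelling of childhood co-morbidity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geo-additive multinomial modelling of childhood co-morbidity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Diarrhoea, fever and cough frequently co-occur in young children, share risk
factors and cluster geographically.  Modelling each illness separately
discards exactly the overlap structure that matters for targeting
interventions.  `morbidmap` therefore treats the three binary indicators as a
single categorical outcome with eight levels — one per combination, with "no
illness" as the reference — and models it with a Bayesian geo-additive
semi-parametric multinomial logit over a set of administrative regions (the
bundled fixture covers Egypt's 27 governorates).

## Model

Let $Y_i \in \{0, 1, \dots, 7\}$ be child $i$'s co-morbidity category
(category 0 = no illness, the reference).  For each non-reference category
$k$,

$$P(Y_i = k) = \frac{\exp(\eta_{ik})}{1 + \sum_{l=1}^{7}\exp(\eta_{il})},
\qquad
\eta_{ik} = z_i^\top \beta_k + \sum_j f_{kj}(v_{ij}) + \theta_{k,r(i)} +
\phi_{k,r(i)},$$

with

* $z_i$ a reference-cell fixed-effect design (intercept plus dummies for the
  categorical covariates: child-age group, sex, residence, maternal-age
  group, BMI group, antenatal visits, place of delivery, working status,
  wealth quintile, mother's education);
* $f_{kj}$ optional smooth functions of metrical covariates (child age in
  months, maternal age at first birth), represented as Bayesian P-splines:
  cubic B-spline bases on equidistant knots (default 20 interior knots)
  with a second-order random-walk prior, i.e. penalty $K = D_2^\top D_2$
  and smoothing variance $\tau^2_{kj}$.  The default model uses **linear
  effects only** and fits the age variables as categorical groups; the
  spline machinery attaches when `smooth_terms` is non-empty;
* $\theta_k$ the *structured* spatial effect with an intrinsic CAR (Markov
  random field) prior: $p(\theta_k \mid \tau^2_{\theta k}) \propto
  \exp\{-\theta_k^\top Q \theta_k / (2\tau^2_{\theta k})\}$, where
  $Q = D - A$ is the graph Laplacian of the region adjacency;
* $\phi_k$ the *unstructured* region effect, iid
  $N(0, \tau^2_{\phi k})$ — together $S_k = \theta_k + \phi_k$ is the usual
  convolution decomposition of regional heterogeneity.

Priors: diffuse Gaussians with precision $\varepsilon = 10^{-6}$ on each
$\beta_k$; conjugate inverse-gamma$(a, b)$ hyperpriors with
$a = b = 0.001$ on every variance.  All of these are exposed in
`model_spec()`.

### Identifiability

The ICAR prior is improper: $Q$ has one null direction per graph component
(the constants).  Each sweep, $\theta_k$ is re-centred to sum to zero and
the subtracted mean is added to the intercept, so $\eta$ is unchanged and
the intercept remains identifiable.  Spline fits are centred the same way
(B-spline rows sum to one, so a constant coefficient shift moves exactly a
constant into the intercept).  The unstructured effect $\phi_k$ carries a
proper prior and needs no constraint.  $\theta$ and $\phi$ are separated
only by their priors — smoothness versus exchangeability — so their split is
weakly identified by construction; the mapped quantity is the structured
component $\theta$, with $\theta + \phi$ available as an option.

## Estimation

`run_mcmc()` is a block Metropolis–Hastings sampler with IWLS-mode
proposals, the sampler family native to structured additive regression
software.  For a coefficient block $\gamma$ with design $X$ and prior
precision $P/\tau^2$, the proposal is drawn from
$N(m, \Phi^{-1})$ with $\Phi = X^\top W X + P/\tau^2$ and
$m = \Phi^{-1} X^\top W (\tilde y - o)$, where $W$ and the working
response $\tilde y$ come from the quadratic (IWLS) approximation of the
multinomial log-likelihood at the current state and $o$ is the offset from
all other blocks.  Because the proposal depends on the current state, the
reverse-move density is recomputed at the proposed state for the
Metropolis–Hastings ratio.  Variances update by their conjugate
inverse-gamma full conditionals, $\mathrm{IG}(a + \mathrm{rank}(P)/2,\;
b + \gamma^\top P \gamma / 2)$.

Block order is fixed: per category $k = 1..7$ — fixed effects, each smooth,
structured effect, unstructured effect; categories couple only through the
multinomial denominator, which the sampler keeps updated incrementally.
The core loop is compiled (RcppArmadillo); region blocks exploit the
incidence structure so no $n \times$ regions matrix is ever formed.  All
randomness flows through R's RNG, so a `model_spec(seed = )` fixes the
chains exactly.

Defaults: 12,000 sweeps, 2,000 burn-in, thinning 10.  Initial values are
deliberately cheap and deterministic: $\beta$ from a one-step
ridge-penalised IWLS fit around the null model, $\theta = \phi = 0$,
variances 0.1.  Acceptance rates are recorded per block; rates outside
[0.05, 0.95] raise a diagnostic warning (IWLS proposals on near-Gaussian
conditionals legitimately sit near the top of that band).

## Posterior summaries

`or_table()` reports the posterior odds ratio of each contrast as
$\exp(\text{posterior mean of the coefficient})$ with an equal-tailed 95%
interval given by $\exp$ of the 2.5%/97.5% coefficient quantiles
(linear-interpolation empirical quantiles).  Summarising on the log-odds
scale and exponentiating afterwards is the convention of the software
family this sampler follows; the alternative — summarising the
exponentiated draws — is implemented behind `scale = "or"` and the choice
is recorded in every output.  Equal-tailed rather than highest-density
intervals are used; with the roughly symmetric coefficient posteriors seen
here the difference is small.  "Significant" means the OR interval
excludes 1; no multiplicity adjustment is applied anywhere in the
descriptive or model layer.

`spatial_effect_table()` gives per-region summaries of $\theta_k$ on both
scales plus a sign-significance flag, one row per region — the
region-to-value contract a choropleth tool consumes.

## The synthetic-data generator

`generate_survey()` is the package's test bed: it draws covariates from
stated marginals, assigns regions uniformly, draws $\theta_k$ from the
intrinsic CAR distribution (exact eigen-decomposition construction with the
null space removed, then centring — exact and cheap at $\le 27$ regions),
draws $\phi_k$ iid normal, computes the multinomial probabilities from the
same predictor the model fits, samples each child's category and back-fills
the three illness flags through the exact inverse of the encoding map.

Its default conditions: $n$ as requested, structured variance 0.3,
unstructured variance 0.1, the 27-governorate graph, near-balanced sex,
rural majority, equal wealth quintiles, child age uniform on 0–60 months.
Covariates are drawn **independently** — the source survey documents no
joint covariate structure, so independence is an assumption of the
generator, not of any data; a `covariate_sampler` hook accepts a
user-supplied joint draw.  Metrical covariates are uniform over their
stated ranges and enter the generator's predictor rescaled to $[0,1]$.

What the generator deliberately does *not* emulate: survey weights,
cluster sampling and stratification (the model ignores them), covariate
dependence, missingness mechanisms, and recall/reporting bias.  Passing
tests on synthetic data therefore demonstrate correct *inference given the
model*, not robustness to those real-data features.

## Numerical choices

* Linear predictors are clamped at $\pm 50$ before exponentiation — far
  outside any plausible posterior region, this only guards `exp()`
  overflow at pathological proposals.
* IWLS weights are floored at $10^{-10}$.
* Chi-squared screening uses the Pearson statistic without continuity
  correction by default (documented switch); expected counts below 5 raise
  a warning rather than switching tests silently.
* Age bins are half-open, left-closed: $[0,20)$, $[20,40)$, $[40,60]$
  months; maternal age splits at 20 years with 20 in the lower group.  The
  underlying analysis names the bins but not boundary membership, so the
  convention is fixed here and recorded in the recode manifest.
* The BMI dichotomy defaults to 18.5 (the WHO underweight cut-point) with
  18.0 supported, because the source description is ambiguous between a
  plain 18 cut-off and the WHO guideline value; neither is presented as
  certain intent.
* Reference levels default to first-alphabetical, overridable per
  covariate and always logged in the design bundle.
* The bundled Egypt adjacency is a hand-curated fixture from public
  administrative geography (no digital adjacency ships with the survey);
  any edge list can be substituted and every run records which graph it
  used.  The survey's area grouping is documented with the six named EDHS
  area labels (urban governorates; Lower/Upper Egypt urban and rural;
  frontier governorates), derived as governorate class crossed with
  urban/rural residence.
* Disconnected graphs are supported opt-in: each component is centred
  separately in the ICAR draw; the default fixture is connected.

## Problem sizes used by the test suite

The suite exercises full parameter recovery at $n = 4{,}000$ children with
12,000 sweeps (the package's reference experiment), interval calibration
over 20 null replicates at $n = 1{,}200$ with 1,500 sweeps each, and
Monte-Carlo distributional checks of the ICAR sampler at 8,000–10,000
draws on a 3-node path graph, where the covariance has a closed-form
oracle (the Moore–Penrose pseudo-inverse of $Q$).  Generator frequencies
are checked at $n = 80{,}000$ against closed-form multinomial-logit
probabilities within three Monte-Carlo standard errors.

## Known limitations

* The $\theta/\phi$ decomposition is identified only through the priors;
  per-region *rankings* of the structured effect are estimated much more
  reliably than its absolute level, and in small regions the posterior
  mean shrinks strongly toward zero.
* No survey weights, no imputation (complete-case only, with logged
  exclusions), no model selection or DIC, and no publication-grade
  cartography — the spatial output is a region-to-value table.
* Categories with very low prevalence (well under 1% of records) carry
  wide posteriors; their odds ratios should be read with their intervals,
  not their point values.
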