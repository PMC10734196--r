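---
title: "Decomposing group gaps in a binary health outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing group gaps in a binary health outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodecomp)
```

## The model and its assumptions

The package quantifies a disparity in a binary outcome between two
population groups. The motivating application is the urban–rural gap in
overweight/obesity (BMI ≥ 25 kg/m²) among women of reproductive age in
a Demographic and Health Survey: one row per woman, a positive sampling
weight restoring population representativeness, a two-level residence
variable, and a set of categorical covariates (wealth quintile group,
age group, education, marital status, religion, employment, media
exposure, contraceptive use, parity, region).

Each group $g \in \{1, 2\}$ gets its own logistic model
$\operatorname{logit} P(Y=1 \mid x) = \beta_0^g + \sum_j \beta_j^g x_j$
on the dummy-coded covariates, fitted by maximizing the
weight-multiplied Bernoulli log-likelihood. The threefold decomposition
of the prevalence gap $D = \bar y^1 - \bar y^2$, taken from the group-2
(rural) viewpoint, is

$$D = \underbrace{\sum_j \beta_j^2(\bar x_j^1 - \bar x_j^2)}_{E}
    + \underbrace{\sum_j \bar x_j^2(\beta_j^1 - \beta_j^2)
      + (\beta_0^1 - \beta_0^2)}_{C}
    + \underbrace{\sum_j (\bar x_j^1 - \bar x_j^2)
      (\beta_j^1 - \beta_j^2)}_{I}.$$

$E$ (endowments) is the part of the gap explained by group differences
in characteristics valued at group-2 coefficients; $C$ (coefficients)
the part due to different returns to the same characteristics,
containing the intercept difference $B$ — the share attributable to
unobservables; $I$ their interaction. Assumptions worth stating
explicitly: the two group models are correctly specified on the
declared dummy coding; sampling weights are the only design feature
honoured (no cluster/stratum variance adjustment); and the
decomposition is an accounting identity, not a causal claim — a large
$E$ for wealth says the wealth mix differs and wealth predicts the
outcome, not that transferring wealth would close the gap.

## Two modes for a binary outcome

The summation formulas above are exact for linear models, but the
outcome model is a logit. The package therefore implements both
conventions and is explicit about which produces which number:

* **`logit_counterfactual`** (default for headline components):
  group-specific weighted logits and counterfactual mean predictions
  $\bar P(X^a, \beta^h)$ — the weighted mean of inverse-logit
  predictions of group $a$'s design under group $h$'s coefficients.
  Then $E = \bar P(X^1,\beta^2) - \bar P(X^2,\beta^2)$,
  $C = \bar P(X^2,\beta^1) - \bar P(X^2,\beta^2)$, and $I = D - E - C$
  is residual-defined, so the additive identity is exact by
  construction. Because each group model has an intercept, the score
  equations force the group mean prediction to equal the weighted
  observed prevalence — which is why reported mean predictions
  match the descriptive prevalence table to full precision.
* **`linear`** (default basis for detailed per-level tables):
  group-specific weighted least-squares linear-probability fits and
  the literal summation formulas, where the identity
  $E + C + I = D$ holds by algebra (tested at $10^{-10}$) and each
  covariate level has an exactly additive part.

When detailed parts are requested from a counterfactual-mode
decomposition, the linear parts are rescaled by a single global factor
per component so they sum to the counterfactual aggregate; within-block
shares are unchanged. This is a presentation convention, not an
estimate of a nonlinear detailed decomposition.

## Detailed contributions and the omitted category

Per-level parts of dummy variables depend on the reference level. The
default (`contrast = "reference"`) reports the non-reference rows
exactly as encoded, plus the `Constant` row carrying $B$. The
alternative `contrast = "deviation"` re-expresses every covariate's
coefficients as deviations from their unweighted level mean (the
intercept absorbs the mean), which removes the dependence on the
omitted category and gives all levels a row; for a binary covariate the
two rows then carry identical endowment parts — the pattern seen in
published tables that report, e.g., equal contributions for "exposed"
and "not exposed" media rows. Both contrasts preserve the block sums
exactly.

## Inference

Confidence intervals are nonparametric bootstrap percentile intervals
(`bootstrap_cis()`, default $B = 200$, 95%). Resampling is stratified
within group by default so both group fits always have data; plain
resampling is available. Replicates whose fits fail (non-convergence,
a resample missing a rare level) are logged and skipped; more than 20%
failures aborts with an "unstable resampling" error rather than
returning intervals from a broken resampling distribution. No
delta-method standard errors are offered — for this estimator the
bootstrap is the honest option at survey sample sizes.

## The synthetic data generator

`synthetic_config()` defines a fully known data-generating process:
group membership Bernoulli($p_1$); categorical covariates drawn
independently within group from group-specific level mixes;
outcome Bernoulli of the inverse-logit of the group's linear predictor;
i.i.d. gamma sampling weights with mean 1 (optionally group-scaled, to
exercise weighted estimators); independent pregnancy and missing-BMI
flags. The emitted table carries a BMI column consistent with the drawn
indicator so the threshold-derivation and exclusion code paths run end
to end; the BMI values themselves are placeholders (uniform within the
WHO bands), not an anthropometric model.

`default_synthetic_config()` fixes the study conditions the package is
tested under: $n = 20{,}000$ by default, 42.1% urban, four covariates
(wealth 3 levels, education 4, media exposure 2, contraceptive use 2)
whose urban mixes are richer, more educated and more exposed, and
group-specific coefficients chosen to give prevalences near 0.35 urban
vs 0.21 rural with an endowment-dominated gap — the qualitative shape
of the published Nigerian estimates. Pregnancy (8%) and missing-BMI
(3%) rates are applied independently of covariates and outcome, so the
exclusions do not shift the estimand.

`compute_truth()` supplies the ground truth two ways: Monte-Carlo over
fresh covariate draws (chunked, with a standard error per component;
the coefficient and intercept pairings share draws so their errors are
paired and small), and exact enumeration of level combinations
(`method = "exact"`), feasible because covariates are independent
within group. The two agree within Monte-Carlo error in the test suite,
which guards each against the other.

What the generator deliberately does **not** emulate: within-group
covariate dependence (no copula), cluster/stratum sampling design,
informative missingness, and continuous covariates. Passing recovery
tests therefore demonstrate estimator correctness under independent
categorical covariates with weights — they do not certify behaviour
under design-based dependence, which the package also does not claim to
handle (weights are the only design feature used).

## Numerical choices

* Logit fits: binomial IRLS (`glm.fit`) with relative-deviance
  tolerance $10^{-12}$, at most 100 iterations; the `converged` flag
  additionally requires the weighted score to satisfy
  $\max_j |X^\top W (y - \hat p)|_j < 10^{-6} \sum_i w_i$.
  Coefficients beyond 15 on the logit scale with a degenerate
  likelihood raise a quasi-separation error instead of returning a
  table of astronomical odds ratios.
* Weights are frequency-style in score and information; they are
  normalized to mean 1 over the fitted subset by default so the
  covariance is comparable across weight scales (point estimates are
  scale-invariant regardless).
* Rank deficiency errors name the collinear columns. A declared level
  absent from the data keeps its all-zero design column (with a
  warning) because counterfactual prediction needs both groups on one
  layout; if that column enters a fit it surfaces as a named
  rank-deficiency error rather than a silent drop.
* Percent contributions are sign-preserving (`100 * part / D`),
  allowing negative shares and shares above 100; they are suppressed
  with a warning when $|D| < 10^{-12}$.
* Chi-square screening uses classical Pearson on unweighted counts
  (this reproduces published test statistics computed from printed
  tables exactly); a weighted-count variant exists but is off the
  default path. A covariate whose outcome margin is degenerate (e.g.
  an all-zero outcome) gets no test rather than an error.
* Rendering rounds half away from zero (percents and chi-squares to 1
  decimal, odds ratios to 2); stored values are full precision, and
  the pipeline writes both.

## Problem sizes in the validation suite

The identity and oracle checks run on samples of 3,000–8,000 records in
seconds. The recovery check estimates all components at
$n = 100{,}000$ against a $10^7$-draw Monte-Carlo oracle and requires
each component within $\max(0.01,\ 3 \cdot \text{bootstrap se})$ of
truth; the coverage check repeats the full bootstrap (B = 200) on 50
independent samples of $n = 20{,}000$ from a two-covariate process and
requires the 95% intervals to cover the exact-oracle truth at least 42
times per component (the 0.999 binomial band around 0.95). These sizes
were chosen as the smallest at which the stochastic criteria are
sharp enough to catch sign and scale errors in any single component.

## Known limitations

* No design-based (linearized or replicate-weight) variance; weights
  affect point estimates only, and bootstrap intervals treat records
  as i.i.d. within strata defined by group.
* The detailed decomposition under the counterfactual mode is a
  rescaled linear allocation, with the caveats above.
* Only the two named exclusion rules (pregnancy, missing BMI) are
  implemented; additional survey-specific cleaning is the caller's
  responsibility, and missing covariate values are listwise-deleted
  with a logged count.
* The twofold (pooled-coefficients) decomposition and sequential
  replacement variants are out of scope.
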