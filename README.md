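# bodecomp

Threefold Blinder–Oaxaca decomposition of binary-outcome disparities in
survey data.

## The problem

Health surveys routinely show large gaps in a binary outcome between two
population groups — the motivating case is the gap in overweight/obesity
(BMI ≥ 25 kg/m²) between urban and rural women of reproductive age in
the 2018 Nigeria Demographic and Health Survey, where weighted
prevalence is about 35.5% in urban areas against 21.1% in rural areas.
The substantive question is *why*: how much of the gap is explained by
the groups having different characteristics (wealth, education, media
exposure, contraceptive use, ...), and how much by those characteristics
having different effects in the two groups?

The Blinder–Oaxaca decomposition answers this by splitting the gap
`D = ȳ¹ − ȳ²` into three components, from the viewpoint of group 2
(rural):

- **Endowment (E)** = Σⱼ βⱼ² (x̄ⱼ¹ − x̄ⱼ²) — the part explained by group
  differences in covariate levels, valued at group-2 coefficients;
- **Coefficient (C)** = Σⱼ x̄ⱼ² (βⱼ¹ − βⱼ²) + (β₀¹ − β₀²) — the part due
  to differences in the returns to characteristics, including the
  intercept ("unobservables") difference **B**;
- **Interaction (I)** = Σⱼ (x̄ⱼ¹ − x̄ⱼ²)(βⱼ¹ − βⱼ²) — their joint term,

so that E + C + I = D. Because the outcome is binary, the package offers
both the literal linear-probability version of these formulas and a
counterfactual-prediction version built on group-specific weighted
logistic fits, where `E = P̄(X¹,β²) − P̄(X²,β²)`,
`C = P̄(X²,β¹) − P̄(X²,β²)` and `I = D − E − C`, with `P̄(X,β)` the
weighted mean inverse-logit prediction of dataset `X` under
coefficients `β`.

Around the decomposition the package provides the full pipeline such an
analysis needs: schema-validated CSV input, BMI-threshold outcome
derivation with pregnancy/missing-BMI exclusions, weighted frequency and
prevalence tables with Pearson chi-square screening, survey-weighted
logistic regression with unadjusted/adjusted odds-ratio tables, detailed
per-covariate-level contributions, and stratified bootstrap percentile
confidence intervals. A synthetic-data generator with a known
group-specific logit data-generating process — and a Monte-Carlo oracle
for the *true* components — makes every stage testable without the
restricted survey microdata.

## Worked example

```r
library(bodecomp)

cfg <- default_synthetic_config(n = 20000, seed = 7)   # DHS-like process
schema <- schema_from_config(cfg)
ds <- apply_exclusions(validate_records(generate_sample(cfg), schema), schema)

decomp <- threefold_decompose(ds, mode = "logit_counterfactual")
print(decomp)
```

```
Threefold decomposition (logit_counterfactual), viewpoint of rural
  mean prediction urban: 0.3797   rural: 0.2324
                coefficient pct_of_D
Difference (D)       0.1473 100.0000
Endowment (E)        0.1000  67.8774
Coefficient (C)      0.0380  25.8317
Interaction (I)      0.0093   6.2908
  intercept share of C (B): +0.0115
```

Read: simulated urban prevalence is 38.0%, rural 23.2%; of the 14.7
point gap, about two thirds is attributable to the urban group's more
favourable covariate mix (endowments) and about a quarter to different
coefficient returns (including unobservables), the rest to their
interaction. The generating truth for this configuration (from
`compute_truth(cfg)`) is D = 0.155, E = 0.084, C = 0.048, I = 0.024 —
the n = 20,000 estimates scatter around it; at n = 100,000 every
component lands within a percentage point (or three bootstrap standard
errors) of the truth — the package's recovery test.

Per-level detail and bootstrap intervals:

```r
detailed_contributions(decomp)               # E/C parts per covariate level
bootstrap_cis(ds, B = 200, seed = 7)         # stratified percentile CIs
```

A configuration-driven run writing all table artifacts:

```r
run_pipeline(list(synthetic = cfg, seed = 7, output_dir = "out"))
```

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/bodecomp.R` (verbs `validate`, `simulate`, `describe`, `fit`,
`decompose`, `run-all`).

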