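# normdev

Normative modeling of global brain features across development, with
Bayesian deviation–psychopathology association.

## What it does, and for whom

Developmental neuroimaging studies increasingly reference each individual
against a *normative model* — the population-expected value of a feature as
a function of age and sex, with its predictive uncertainty — instead of
comparing group means. `normdev` implements that workflow end to end for
global brain features (skeleton-mean FA, MD, RD, L1 from diffusion MRI;
mean cortical thickness and total surface area from structural MRI) plus a
general cognitive factor, and then asks how individual deviations relate to
dimensional psychopathology and cognition. It is aimed at researchers who
want a tested, reproducible pipeline for deviation-score analyses on
tabular per-subject data, and at methodologists who want the estimators
validated by parameter recovery on synthetic cohorts with known ground
truth.

## The model

For each feature `y`, a Bayesian linear regression

    y = Φ w + ε,   w ~ N(0, α⁻¹ I),   ε ~ N(0, β⁻¹ I)

is fitted, where `Φ` contains an intercept, age, sex, and a clamped cubic
B-spline expansion of age with three evenly spaced interior knots.
Hyperparameters `(α, β)` maximize the log marginal likelihood via a Powell
search over `(log α, log β)`. Each subject's deviation is the
cross-validated Z-score

    Z = (y − ŷ) / sqrt(σ̂²),   σ̂² = 1/β + φᵀ Σ_w φ,

computed 10-fold out of sample. Behavioral structure comes from the first
principal component of a 14-test cognitive battery (itself normatively
modeled, giving `COG_dev`) and from seven stability-resampled ICA
components of 129 psychopathology items plus their mean (the
general-psychopathology proxy). Each (deviation, behavioral score) pair is
then modeled as

    z = b₀ + b_age·age* + b_sex·sex + b_dom·dom* + ε,   b_dom ~ N(0, 1),

(`*` = standardized) and the evidence for `b_dom = 0` is the Savage–Dickey
density ratio `BF01 = p(b_dom = 0 | data) / p(b_dom = 0)`, labeled with the
standard anecdotal/moderate/strong/very strong/extreme bands on both the
alternative (< 1) and null (> 1) sides.

Because the cohorts such analyses run on are restricted-access, the package
includes a synthetic cohort generator with known age trajectories, a known
cross-feature latent deviation structure, an ordinal item model for the
questionnaire, and injectable deviation–domain effects — so calibration,
coverage and recovery are all testable. See the vignette
(`vignettes/normative-deviation-modeling.Rmd`) for the full methods
account.

## Worked example

```r
library(normdev)
cfg <- default_config(n = 500, seed = 1)   # simulate a 500-subject cohort
run <- run_pipeline(cfg)
print(run)
```

```
normdev pipeline run: 500 subjects
cognitive general factor: 52.1% of battery variance
out-of-sample explained variance by feature:
  FA    38.6%  (SMSE 0.614, MSLL -0.243, rho 0.621)
  MD    39.4%  (SMSE 0.606, MSLL -0.249, rho 0.628)
  RD    36.7%  (SMSE 0.633, MSLL -0.228, rho 0.606)
  L1     7.3%  (SMSE 0.927, MSLL -0.035, rho 0.273)
  CT    29.3%  (SMSE 0.707, MSLL -0.170, rho 0.541)
  SA    19.0%  (SMSE 0.810, MSLL -0.103, rho 0.437)
  COG   19.1%  (SMSE 0.809, MSLL -0.103, rho 0.437)
ICA stability: 0.90 0.86 0.89 0.80 0.88 0.86 0.87
association grid: 54 models, 1 with extreme evidence (BF01 < 0.01)
strongest association: SA_dev ~ COG_dev  (B = +0.273, BF01 = 1.41e-07, extreme (alternative))
```

Reading this output: age and sex explain 7–39% of out-of-sample variance
per feature (the trivial predictor would explain 0%; negative MSLL means
the model beats it in log loss). The seven ICA components are highly
reproducible across bootstrap resamples (stability 0.80–0.90; pure noise
sits below 0.5). Of the 54 deviation × behavior models, the strongest
association is between the surface-area deviation and the cognitive
deviation (`B = 0.273`: a 1 SD higher cognitive deviation predicts a 0.27
higher surface-area Z), with extreme evidence against the null — this is
the generator's built-in SA–cognition coupling being recovered. The
per-pair table is in `run$associations`:

```r
head(run$associations[order(run$associations$BF01), ], 3)
#>    feature  domain     B ci_low ci_high     BF01                  label
#> 54  SA_dev COG_dev 0.273  0.187   0.358 1.41e-07  extreme (alternative)
#> 9   FA_dev COG_dev 0.134  0.046   0.222 2.59e-01 moderate (alternative)
#> 7   FA_dev     IC7 -0.122 -0.210  -0.035 5.38e-01 anecdotal (alternative)
```

and `run$correlations$r` holds the deviation-score Pearson matrix (e.g.
`FA_dev`–`RD_dev` = −0.69 at these noise settings). With
`cfg$output_dir <- "out"` every stage table is written as CSV along with a
JSON run report; the same run is available from a shell via

```sh
Rscript inst/cli/normdev.R run --seed 1 --out out
```

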