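# carbondyn

Palaeodemographic time-series analysis in R: from radiocarbon date lists
to summed probability distributions (SPDs), and from SPDs to fitted
competition–cooperation population-dynamic models with exogenous
covariates, AICc multimodel inference, and total-trajectory validation.

The package is aimed at archaeologists and population ecologists who want
to test *mechanistic* hypotheses about prehistoric population change —
competition for limiting resources, Allee-like cooperation, hydroclimate
forcing, warfare, social upscaling — against radiocarbon-based population
proxies, rather than describe trends visually.

## The model

Under the "ages as data" premise, the density of archaeological
radiocarbon dates tracks past human activity, so the SPD of calibrated
dates is a relative population proxy `x_t`. Writing `X_t = log x_t` and
the per-generation growth rate `R_t = X_{t+1} − X_t` (25-year steps), the
package fits the discrete-time growth-rate family

```
R_t = R_m − (c + α₀ z_t + α₁ z′_t) · e^{X_t} − (w + β₀ z″_t + β₁ z′_t) · e^{−X_t}
```

where `R_m` is the logarithmic maximum reproductive rate, `c` the
intensity of intra-population competition (a Ricker-type density
dependence), `w` the intensity of cooperation needed to overcome
environmental hazards (an Allee-like `1/x` term), and `z, z′, z″` are
observed covariates: a hydroclimate proxy (terrestrial lithic
concentrations), a warfare index (min–max-merged skeletal trauma
frequencies), and a social-upscaling index (min–max-merged Pb/Hg
enrichment factors). Four nested candidates are compared:

| model | covariates on `c` | covariates on `w` |
|-------|-------------------|-------------------|
| A     | —                 | —                 |
| B     | hydroclimate, warfare | —             |
| C     | hydroclimate, warfare | social upscaling |
| D     | hydroclimate, warfare | social upscaling, warfare |

The family is linear in its parameters given the data, so fits are exact
ordinary least squares; models are ranked by small-sample AICc and Akaike
weights, and validated by simulating the *entire* trajectory from the
first observed value only, scored with the coefficient of prediction
`σ² = 1 − Σ(Ô_i − O_i)² / Σ(Ō − O_i)²`.

The SPD side implements per-date calibration against any `.14c`-format
curve, 50-year complete-linkage site binning, annual summation, and a
100-year centered rolling mean, in normalized and unnormalized variants.
A synthetic-data module generates known-truth trajectories, radiocarbon
date collections sampled from them, and smooth bounded covariate series,
so the entire pipeline is testable without any download.

## Worked example

Fit the four candidate models to a known-truth synthetic series at the
noise scale implied by the published full-model AICc:

```r
library(carbondyn)

cov <- covariate_draw(1)   # lithic, warfare, pollution series
cfg <- truth_config(noise_sd = aicc_implied_noise_sd(-109.61, 54, 7), seed = 1)
tab <- generate_truth_trajectory(cfg, cov$lithic, cov$warfare, cov$pollution)

fits <- lapply(model_family(), fit_model, table = tab)
model_selection(fits)
#> AICc model selection (n = 54 ):
#>  model n_params    rss    aicc delta_aicc    weight rank
#>      D        7 0.1764 -136.65       0.00 9.974e-01    1
#>      B        5 0.2469 -123.90      12.75 1.701e-03    2
#>      C        6 0.2410 -122.58      14.07 8.782e-04    3
#>      A        3 1.2990  -39.22      97.43 6.956e-22    4
#> Predictor relative importance:
#>    lithic_on_c   warfare_on_c pollution_on_w   warfare_on_w
#>          1.000          1.000          0.998          0.997

validate_trajectory(fits$D, tab)$sigma2
#> [1] 0.93
```

The generating model (D) takes essentially all the Akaike weight, every
covariate predictor has relative importance near 1, and the
total-trajectory simulation started from the first observed value alone
explains 93% of the variance of the log series.

The same comparison can be run end to end from files — dates CSV,
calibration curve, proxy CSVs — with `run_pipeline()`:

```r
bundle <- synthetic_bundle(tempfile(), truth_config(seed = 1))
report <- run_pipeline(bundle$paths)
report$fit_table   # parameters, AICc, ΔAICc, w_i, σ² per model and variant
```

Note that recovery through a full SPD is much harder than at the series
level: sampling 400 dates, calibration error and the 100-year rolling
mean suppress generation-scale growth-rate structure, and the best model
is no longer guaranteed to win — see the methods vignette
(`vignettes/competition-cooperation-spd.Rmd`) for a discussion of this
limitation.

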