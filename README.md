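# adforecast

Forecasting daily atopic dermatitis (AD) severity, and asking whether the
environment helps.

AD severity is tracked in panel studies as six daily ordinal sign scores —
dryness, oedema, itching, oozing, redness, sleep disturbance, each on a
0 (none) to 4 (severe) scale — alongside topical corticosteroid (TCS) use and
daily environmental exposures (mean temperature, relative humidity, rainfall,
diurnal temperature range, PM10, NO2, O3). `adforecast` implements a
probabilistic one-day-ahead forecasting pipeline for such data and the
predictive test of whether exposures add information beyond today's scores.

## The model

For patient *k* and sign score *s⁽ᵏ⁾(t) ∈ {0,…,4}*:

    s⁽ᵏ⁾(t+1) ~ OrderedLogistic( α⁽ᵏ⁾ + Σᵢ βᵢ 1{s⁽ᵏ⁾(t)=i} + γᵀx⁽ᵏ⁾(t),  c ),
    α⁽ᵏ⁾ ~ N(0, σ²_α),   i = 0,…,3

a mixed-effect autoregressive ordinal logistic regression: the four βᵢ carry
day-to-day persistence (score 4 is the reference), the patient random
intercept α⁽ᵏ⁾ carries heterogeneity, c are the ordered-logistic cut-offs and
γ the covariate effects (covariates at day *t* predict day *t+1*; continuous
covariates z-scored on the training window). One model per sign is fitted to
pairs of successive scores by maximum marginal likelihood with adaptive
Gauss–Hermite quadrature (C++ core, analytic gradients).

Validation is by forward chaining — train on everything strictly before day
*T*, forecast day *T*, slide onward — scored with the ranked probability
score (RPS, normalised to [0, 1]) against two benchmarks: the uniform
forecast (1/5 each) and the patient's own historical frequencies. The six
sign forecasts combine, under independence, into an exact probability for the
binary AD symptom state (itching + sleep ≥ 2 and ≥ 2 of the four other signs
non-zero), scored with the Brier score. Covariate value is judged by paired
per-forecast RPS differences with Diebold–Mariano (HAC) intervals.

Because the motivating cohort (177 children followed daily for ~17 months in
Seoul) is not publicly deposited, the package ships a calibrated synthetic
cohort generator with the same structure — persistence, patient
heterogeneity, sign-specific marginal imbalance (~90% zeros for oedema),
18.9% missing scores, seasonal AR(1) environmental series, severity-driven
TCS use — with known ground truth, so the whole pipeline is testable.

## A worked example

```r
library(adforecast)

cfg    <- generator_config(n_patients = 30, n_days = 90, seed = 1)
cohort <- generate_cohort(cfg)
ds     <- filter_min_observations(cohort$panel, min_days = 10)
print(ds)
#> <ad_panel> 30 patients, 2700 patient-day rows (2700 with >=1 observed sign)
#>   days 1..90; covariates: temp, rh, rainfall, dtr, pm10, no2, o3, tcs
#>   missing sign-score cells: 18.9%

tab <- forward_chaining(
  ds,
  variants = list("no-covariate" = character(), "single:temp" = "temp"),
  refit_stride = 7, min_train_days = 21)
print(tab)
#> <score_table> 33408 records; 30 patients, days up to 90
#>   variants: no-covariate, single:temp, uniform, historical
#>   mean Brier historical       0.1898
#>   mean Brier no-covariate     0.1357
#>   mean Brier single:temp      0.1330
#>   mean Brier uniform          0.4471
#>   mean RPS   historical       0.0843
#>   mean RPS   no-covariate     0.0620
#>   mean RPS   single:temp      0.0622
#>   mean RPS   uniform          0.2253
```

Reading this: the autoregressive model cuts the RPS of the best benchmark by
about a quarter (0.062 vs 0.084 — lower is better) and beats it clearly on
the binary state (Brier 0.136 vs 0.190), while the temperature-augmented
variant is
indistinguishable from the covariate-free model. The paired comparison makes
that explicit — every 95% interval covers zero:

```r
paired_score_difference(
  tab[tab$model_variant == "no-covariate" & tab$sign != "state", ],
  tab[tab$model_variant == "single:temp"  & tab$sign != "state", ])
#>      sign    n mean_diff       se     lower    upper
#> 1 dryness 1331 -1.77e-04 1.65e-04 -0.000500 1.46e-04
#> 2 itching 1384 -1.59e-04 1.20e-04 -0.000393 7.60e-05
#> 3  oedema 1335 -4.01e-04 2.87e-04 -0.000964 1.62e-04
#> 4  oozing 1307 -2.42e-05 1.71e-04 -0.000359 3.11e-04
#> 5 redness 1417 -2.85e-05 6.02e-05 -0.000146 8.94e-05
#> 6   sleep 1416 -1.38e-04 2.53e-04 -0.000633 3.58e-04
```

(`mean_diff > 0` would mean the covariate model forecasts better.)
`plot_learning_curves(tab, "dryness")` draws the smoothed per-day score
curves with ±1.96 SE bands; `run_simulate()` / `run_validate()` /
`run_report()` chain the whole pipeline from a YAML configuration, and
`inst/scripts/adforecast.R` wraps them for the shell.

## Documentation

The methods vignette (`vignettes/modelling-daily-ad-severity.Rmd`) documents
the model and estimator, the validation design, every tunable default, the
synthetic-data assumptions and what they do and do not demonstrate, and known
limitations.
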