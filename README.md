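# ppgr — free-living postprandial glucose responses

`ppgr` is an R package for meal-level analysis of free-living glycemic
data. It is aimed at studies that combine smartphone food logging
(ecological momentary assessment, EMA), continuous glucose monitoring
(CGM), wrist accelerometry and sleep detection over multi-day wear
periods, and that ask: *which lifestyle behaviours — meal composition,
postprandial and daily physical activity, sleep, time of eating — go
with smaller glucose excursions after meals, within and between
people?*

The package:

1. reconstructs timestamped meals from EMA responses and applies the
   inclusion rules (time-matched CGM coverage; no other intake within
   2.5 h before; eaten 06:00–24:00; at least three qualifying meals per
   participant);
2. computes the outcome — the 2-h postprandial incremental area under
   the glucose curve (iAUC, mmol/l·min, trapezoidal rule above the
   meal-time baseline) — and the pre-prandial 2-h mean;
3. classifies 5-s ENMO epochs by the 40/100 mg cut-points and derives
   meal-anchored exposures: LPA and MVPA hours in `(t, t+2h]` and
   `[t−24h, t)`, and prior-night sleep duration;
4. splits every longitudinal exposure into between-person (person
   mean) and within-person (deviation) components, with ICC variance
   decompositions;
5. fits random-intercept linear mixed models of iAUC on the exposure
   pairs plus covariates, in a per-exposure *basic* mode and a
   mutually-adjusted *full* mode, with cluster-bootstrap percentile
   CIs, sex/prediabetes interaction tests and stratified refits.

For a meal *j* of participant *i* the full model is

```
iAUC_ij = β0 + Σ_e [ βw_e (x_eij − x̄_ei) + βb_e x̄_ei ]
        + τ(time-of-day) + γ'z_i + b_i + ε_ij ,   b_i ~ N(0, σ²_b)
```

where `x_e` ranges over 15 food-group flags, satiety, postprandial and
daily LPA/MVPA and sleep, and `z_i` are baseline covariates (age, sex,
ethnicity, education, smoking, alcohol, BMI, pre-prandial glucose).

Because the motivating dataset is not public, the package ships a
seeded synthetic-cohort generator (`simulate_cohort()`) that emulates
the study design — 9 free-living days, six EMA prompt windows per day,
15-min CGM, 5-s epochs — with a known linear ground truth
(`ground_truth()`), so every stage is testable by parameter recovery.
See the methods vignette (`vignettes/free-living-postprandial-glucose.Rmd`)
for the model, the generator's calibration and the design decisions.

## Worked example

Simulate a 150-participant cohort with the default ground truth, run
the whole pipeline, and look at the fitted full model:

```r
library(ppgr)

run <- run_pipeline(ppgr_config(
  simulate = list(n_participants = 150), seed = 1,
  models = list(bootstrap = TRUE, B = 200, basic = FALSE),
  icc = list(measures = c("iauc_2h", "refined_grains", "pp_mvpa_h", "sleep_h"))
))
#> simulated cohort: 150 participants, seed 1
#> EMA responses: 2871; parsed meal records: 2871
#> qualified meals: 2715 of 2871; retained participants: 150 of 150
#> analysis events: 2715 rows
#> variance decomposition: 4 measures
#> full model: 55 fixed effects, converged=TRUE
#> bootstrap: B=200, failed=0

tidy(run$fit_full, conf_int = run$ci_full)
#>   term                             estimate conf.low conf.high   p.value
#> 1 refined_grains_w                    43.48    39.18     48.01  4.9e-71
#> 2 whole_grains_w                      24.93    18.59     30.82  1.8e-16
#> 3 satiety_w                           10.05     7.08     13.03  7.4e-12
#> 4 pp_lpa_h_w                         -29.50   -39.72    -20.67  7.6e-08
#> 5 pp_mvpa_h_w                        -60.13   -72.52    -47.38  3.6e-13
#> 6 sleep_h_w                           -1.58    -3.28      0.69  0.084
#> 7 time_categoryafternoon_1200_1800    52.43    48.68     56.32  3.0e-114
#> 8 time_categoryevening_1800_2400      41.28    36.61     45.97  6.1e-76
```

Reading this: meals containing refined grains run about 43 mmol/l·min
higher in 2-h iAUC than the same person's meals without them (the
generating truth is +46.2); an hour of moderate-to-vigorous activity in
the 2-h postprandial window is associated with about −60 (truth −58);
afternoon meals exceed morning meals by about +52 (truth +54.4). The
`_w` suffix marks within-person effects — each participant acting as
their own control.

```r
glance(run$fit_full)
#>   n_meals n_participants icc  converged singular
#> 1 2715    150            0.29 TRUE      FALSE

run$vardecomp[, c("measure", "scale", "within_share")]
#>   measure        scale          within_share
#> 1 iauc_2h        continuous     0.76
#> 2 refined_grains binary_latent  0.90
#> 3 pp_mvpa_h      continuous     0.77
#> 4 sleep_h        continuous     0.60
```

Roughly three quarters of the variance in postprandial responses (and
most of the variance in the lifestyle exposures) is within-person —
the motivation for analysing both levels separately. Plot helpers:
`autoplot(run$fit_full, conf_int = run$ci_full)` (forest plot),
`plot_variance_decomposition(run$vardecomp)`,
`plot_stratified(stratified_fit(run$events, "sex"))`.

Real data enter through the `inputs` branch of `ppgr_config()` as five
CSV files (EMA responses, CGM readings, ENMO epochs, sleep windows,
participant table); `write_cohort()` documents the exact schemas by
example.

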