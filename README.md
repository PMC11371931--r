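# glucodyn

Personalized modeling of insulin-regulated glucose metabolism from oral
glucose tolerance test (OGTT) and continuous glucose monitoring (CGM) data.

## What it does

A 7-point OGTT samples plasma glucose and insulin at t = 0, 15, 30, 45, 60,
90, 120 min after a 75 g glucose drink; a CGM sensor records interstitial
glucose every 5 minutes over the same window. `glucodyn` calibrates a
compartmental glucose-insulin ODE model to each person's response and asks
whether the minimally invasive CGM trace can stand in for the plasma glucose
samples without changing what the model estimates.

The model tracks gut glucose mass, plasma glucose `G`, plasma and remote
insulin, and interstitial glucose `G_i`, which lags plasma through

```
dG_i/dt = (G - G_i) / tau_g
```

Per response, calibration estimates `k1` (rate of glucose appearance in the
gut, 1/min), `k5` (rate of insulin-dependent glucose uptake, i.e. insulin
sensitivity), `k6` (gain of glucose-dependent insulin secretion), and — when
fitting the CGM trace — the equilibration lag `tau_g` (min). The objective
is max-normalized least squares over the fitted channels,

```
L(theta) = sum_i sum_j ((y_ij - yhat_ij) / max(y_i))^2 ,
```

minimized by a TikTak-style multistart (Sobol global scan, sequential
bounded local polishes blended toward the incumbent). Practical
identifiability is assessed per fit by profile likelihood, with
prediction-profile confidence bands for the observables, and fasting/OGTT
indicator formulas (Matsuda, HOMA-IR, HOMA-beta, insulinogenic index,
AUC 0-30, HIRI, MISI, oral disposition index) provide the clinical
reference frame. Because the motivating clinical cohort is access
restricted, a synthetic cohort generator with known ground truth, realistic
sensor noise, missingness and the study's exclusion rules is a first-class,
tested module.

## Worked example

```r
library(glucodyn)

# a reproducible synthetic subject: true parameters + noisy OGTT and CGM data
spec   <- cohort_spec(n_subjects = 1, seed = 21)
subject <- sample_cohort(spec)[[1]]
round(subject$truth, 4)
#>     k1     k5     k6  tau_g
#> 0.0211 0.0086 2.4037 0.7011

# calibrate on plasma glucose + insulin, then on CGM glucose + insulin
fit_pl <- calibrate_response(build_observations(subject$response, "plasma"),
                             calibration_config("plasma"))
fit_pl
#> <edes_fit> mode = plasma
#>   estimates: k1 = 0.02109, k5 = 0.008818, k6 = 2.421
#>   objective: 0.00952975  | boundary hits: 0

fit_cgm <- calibrate_response(build_observations(subject$response, "cgm"),
                              calibration_config("cgm"))
glance(fit_cgm)[c("objective", "mse_glucose", "mse_insulin")]
#> # A tibble: 1 x 3
#>   objective mse_glucose mse_insulin
#>       <dbl>       <dbl>       <dbl>
#> 1    0.0315      0.0657        11.7
```

Both calibrations land within a few percent of the generating parameters;
the CGM fit additionally recovers the interstitial lag (`tau_g` = 1.3 min
estimated against 0.7 min true for this subject — the lag is the least
determined quantity at 5-min sampling). Profile likelihood classifies the
fit:

```r
profs <- lapply(c("k1", "k5", "k6"), function(p) profile_parameter(fit_pl, p))
classify_identifiability(profs)
#> # A tibble: 3 x 6
#>   parameter   lower   upper lower_bounded upper_bounded identifiable
#> 1 k1        0.0195  0.0228  TRUE          TRUE          TRUE
#> 2 k5        0.00831 0.00931 TRUE          TRUE          TRUE
#> 3 k6        2.19    2.69    TRUE          TRUE          TRUE
```

All three confidence intervals are finite inside the scan range, so the
model is practically identifiable from this response; dropping the insulin
channel (`drop_metabolite(obs, "insulin")`) leaves the secretion gain `k6`
with an unbounded interval, and the same machinery flags it. Cohort-scale
comparison runs through `run_cohort()` + `build_report()`:

```r
cohort  <- apply_exclusions(sample_cohort(cohort_spec(20, seed = 101)))$kept
results <- run_cohort(cohort, modes = c("plasma", "cgm"))
report  <- build_report(results, cohort_indicators(cohort))
report$param_spearman   # cross-mode agreement of k1, k5, k6
report$mse_summary      # fit quality per mode and observable
```

`tidy()`, `glance()` and `autoplot()` methods cover fits, profiles, bands
and trajectories; `write_cohort_csv()` / `read_cohort_csv()` define the
plain-text interchange format, and `inst/cli/glucodyn.R` exposes the
generate / calibrate / indicators / report steps as a command-line
pipeline.

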