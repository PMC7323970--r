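# agrisuit

Agro-climatic crop suitability modelling under climate change, in R.

`agrisuit` is for analysts who need to map where staple crops (maize,
sorghum, cassava, groundnut in the bundled defaults) can be grown today
and how that geography shifts under projected climate — at national
scale, from nothing more than daily gridded weather, a soil-carbon
surface, and district yield statistics.

## What it computes

1. **Suitability classes from yield percentiles.** Per crop, district
   mean yield over the record is quartered at the 25th/50th/75th
   percentiles of the national district-mean distribution into four
   ordinal classes — *limited* (rank 1), *marginal* (2), *moderate* (3),
   *optimal* (4, mean yield ≥ q75) — and every crop-masked pixel
   inherits its district's class.
2. **Eight biophysical predictors** from daily weather: growing-season,
   March–September and sowing-month rainfall sums (mm, zone-specific
   calendar windows), the coefficient of variation of monthly
   March–September rainfall (%), mean diurnal temperature range (°C),
   growing-season and March–September mean temperatures (°C), and
   topsoil organic carbon (t/ha).
3. **A four-class gradient-boosted tree classifier** (softmax objective,
   implemented from scratch in Rcpp) mapping the eight predictors to
   class, tuned by stratified cross-validated grid search over boosting
   rounds, tree depth and learning rate on a stratified 70/30 split.
4. **Evaluation from the held-out confusion matrix:** overall accuracy
   (trace/total), kappa ((p_o − p_e)/(1 − p_e)), pairwise-average
   (Hand–Till) multiclass AUC, and eleven one-vs-rest per-class metrics.
5. **Gain-based variable importance**, standardized to shares summing to
   1, with rainfall/temperature/soil group totals.
6. **Scenario projection:** additive per-GCM climate deltas (bundled
   national table for four GCMs × RCP2.6/RCP8.5) applied to the baseline
   predictors (soil unchanged), prediction of future class maps, and
   multi-model mean area-change tables.
7. **Multi-crop aggregation:** per-pixel counts of crops per class
   level, combined rank-sum scores (4–16 for four crops), pairwise
   scores (2–8, categories `Ld-Ld` … `Op-Op`), and area/percentage
   accounting.

A seeded synthetic-data module generates daily weather grids with a
north (unimodal, August-peak) vs south (bimodal, May/October) rainfall
climatology calibrated to a 1246 mm March–September total, district
partitions, soil surfaces, and yield series driven by a known predictor
— so the whole pipeline runs and is testable with no external data.

## Worked example

Recover a known suitability driver from synthetic data: class is a noisy
monotone function of growing-season rainfall (noise calibrated so the
Bayes-optimal accuracy is ≈ 0.85), the other seven predictors carry no
signal.

```r
library(agrisuit)
samples <- generate_recovery_samples(2000, driver = "rain_growing_season", seed = 1)
parts   <- split_samples(samples, fraction = 0.7, seed = 1)
model   <- tune_and_fit(parts$fit,
                        grid = expand.grid(nrounds = c(50L, 100L),
                                           max_depth = c(2L, 4L),
                                           eta = c(0.1, 0.3)),
                        nfolds = 3, seed = 1)
model
#> <suitability_model> 4 classes; rounds=50 depth=2 eta=0.1 (cv acc 0.839)

rep <- metrics_report(factor(as.character(parts$test$class),
                             levels = suitability_levels()),
                      predict(model, parts$test),
                      predict(model, parts$test, type = "prob"))
round(rep$overall, 3)
#>      oa kappa   auc
#> 1 0.822 0.762 0.965

head(gain_importance(model), 3)
#>               variable       gain       share
#> 1  rain_growing_season 7970.07424 0.961567973
#> 2    rain_sowing_month  101.13677 0.012201879
#> 3 tmean_growing_season   52.32759 0.006313182
```

Held-out accuracy (0.82) sits just under the Bayes ceiling of the
generating process, and the true driver absorbs 96% of the ensemble's
split gain — the pipeline recovers both the signal and its source.
Multi-model scenario summaries come straight from the bundled delta
table:

```r
s <- summarize_deltas(ghana_climate_deltas())
s[s$scenario == "RCP2.6", c("variable", "mean_delta", "n_agree")]
#>               variable mean_delta n_agree
#> 1         rain_mar_sep     15.750       2
#> 2    rain_sowing_month      9.000       4
#> 3              rain_cv      2.500       3
#> 4  rain_growing_season     17.750       3
#> 5          dtr_mar_sep     -0.325       4
#> 6 tmean_growing_season      1.650       4
#> 7        tmean_mar_sep      1.375       4
```

(`round_half_up()` converts these to reporting precision: +16 mm
Mar–Sep rain, −0.3 °C diurnal range, +1.7 °C growing-season warming;
all four GCMs agree on warming.)

The full pipeline — simulate, derive variables, class yields, fit one
model per crop, evaluate, project both RCPs per GCM, aggregate
multi-crop scores, and write CSV artifacts plus a hashed manifest — is
one call:

```r
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

A thin command-line wrapper is available as
`Rscript scripts/agrisuit.R run --seed 1 --out run1`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's full synthetic pipeline from scratch at the
given seed (all four crops, both scenarios, all four GCMs), logs
per-crop evaluation metrics, and writes the results JSON. The methods
vignette (`vignettes/agro-climatic-suitability.Rmd`) documents the
model, the synthetic world and every numerical convention.
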