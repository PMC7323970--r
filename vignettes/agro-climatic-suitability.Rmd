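---
title: "Modelling agro-climatic crop suitability under climate change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling agro-climatic crop suitability under climate change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Rain-fed crop production in tropical West Africa is constrained by where
and when rain falls, by temperature regimes, and by soil fertility. This
package implements a national-scale empirical suitability analysis for
staple crops (maize, sorghum, cassava, groundnut are the bundled
defaults): district yield statistics define four ordinal suitability
classes, a gradient-boosted tree classifier learns the mapping from
biophysical predictors to class, and additive climate-change deltas from
general circulation models (GCMs) project how the classes shift by
mid-century. Because the underlying observational inputs (daily satellite
rainfall, reanalysis temperatures, ministry yield returns) are not
redistributable, a seeded synthetic-data module emulates their structure
so that every stage of the pipeline is testable offline, end to end, with
known ground truth.

```{r, eval = FALSE}
library(agrisuit)
res <- run_pipeline(default_config(seed = 1), out_dir = "run1")
```

## Suitability classes from yield percentiles

For each crop, district mean yield over the record (11 years by default,
2006--2016 framing) is quartered at the 25th/50th/75th percentiles of the
national district-mean distribution:

* **limited** (rank 1): mean yield below the 25th percentile;
* **marginal** (2): between the 25th and 50th;
* **moderate** (3): between the 50th and 75th;
* **optimal** (4): at or above the 75th percentile.

Two conventions had to be fixed where prose leaves them open. Intervals
are half-open from below, with the optimal class closed at the 75th
percentile (`y >= q75`); for continuous yields any other convention
changes only measure-zero cases. Percentiles use linear interpolation
between order statistics (R's default type 7), with a nearest-rank switch
(`yield_thresholds(..., type = "nearest")`). Classes are computed
nationally per crop, then every crop-masked pixel inherits its district's
class (`rasterize_labels()`), so the training examples are pixels. This
pseudo-replicates district information across pixels; whether the original
analysis trained on pixels or district aggregates is not recoverable, and
the pixel route is the one consistent with per-pixel class assignment.

## The eight biophysical predictors

`assemble_variables()` derives, per pixel (units in brackets; windows are
calendar dates resolved per year and averaged across years):

1. growing-season rainfall sum [mm] — 24 May--30 Sep in the north,
   1 Mar--30 Jun in the south;
2. March--September rainfall sum [mm] — 1 Mar--30 Sep, both zones;
3. sowing-month rainfall sum [mm] — 24 May--30 Jun north (38 days, as
   specified), 1 Mar--30 Apr south;
4. rainfall coefficient of variation [%] — 100 x sd/mean of the monthly
   rainfall sums for Mar--Sep, pooled over years (77 values for 11
   years); the sample (n-1) standard deviation is the default with a
   `cv_std = "population"` switch, since the convention is unstated;
5. diurnal temperature range [degC] — mean of tmax - tmin, 1 Mar--30 Sep;
6. growing-season mean temperature [degC] — zone windows as in (1);
7. March--September mean temperature [degC];
8. topsoil organic carbon [t/ha] — copied through unchanged.

Daily mean temperature is `(tmax + tmin)/2`, as min/max is what the
emulated sources provide. Calendar month-day pairs are authoritative:
day-of-year annotations drift by one across leap years and are not used.
A pixel with zero mean monthly rainfall has an undefined CV; it is
returned as `NaN`, warned about, and dropped from the training samples
(`build_samples()` counts the drops) rather than silently zeroed.

## The classifier

`gbt_fit()` is a from-scratch second-order gradient-boosting
implementation with the multiclass softmax objective (no boosting library
is assumed): per round one depth-limited regression tree per class is fit
to the gradient/hessian of the log-loss, leaf weights are
`-G/(H + lambda)` scaled by the learning rate, and splits maximize the
usual regularized gain by exact greedy search. Ties between candidate
splits resolve to the lowest feature index and threshold, so training is
bit-reproducible. The three tuned axes are boosting rounds, maximum tree
depth and learning rate, searched over
`default_tuning_grid()` (rounds {50, 100, 200}, depth {2, 4, 6}, learning
rate {0.05, 0.1, 0.3}) by stratified 5-fold cross-validated accuracy;
fold count, grid and the scoring metric are configurable. A "sigma"
parameter is sometimes named as the third tuned axis in this kind of
analysis; sigma belongs to kernel methods, not boosted trees, and the
learning rate is the standard third axis, so that is what is tuned.

The 70/30 fit/test split is stratified by class by default (guaranteeing
all four classes on both sides; `stratify = FALSE` gives a simple random
split). Hard labels are the argmax of the softmax probabilities; the
probabilities themselves feed the multiclass AUC.

## Evaluation metrics

All metrics are computed from the held-out confusion matrix (rows =
reference): overall accuracy (trace/total), the kappa coefficient
`(p_o - p_e)/(1 - p_e)`, and eleven one-vs-rest per-class statistics
(sensitivity, specificity, PPV, NPV, precision, recall, F1, prevalence,
detection rate, detection prevalence, balanced accuracy). Zero
denominators yield `NaN` with a count of affected classes — never a
silent 0. The multiclass AUC is the pairwise-average construction: for
each unordered class pair, the two-class rank-statistic AUC of each
class's score on the pair's samples, averaged within the pair and then
over pairs, with ties counted 0.5. Probability scores are used (hard
labels would degenerate the ranking). When `p_e = 1` kappa is undefined;
the implementation reports 1 for perfect agreement and otherwise 0 with a
warning.

## Variable importance

Gain importance sums each predictor's split-gain contributions across
every tree, standardized to shares summing to 1 (the reading of
"standardized between 0 and 1" that makes shares additively comparable;
a max-normalized variant is behind `normalize = "max"`). Grouped totals
are reported for both rainfall groupings — including and excluding the
rainfall CV from the rainfall group — because "rainfall-related factors"
is genuinely ambiguous about the CV; neither total is privileged.

## Climate scenarios

`ghana_climate_deltas()` bundles the national per-GCM additive changes
(four GCMs x RCP2.6/RCP8.5) for the seven climate-derived predictors;
soil organic carbon is assumed unchanged for lack of projections.
`apply_delta()` adds deltas uniformly in space (the national-summary
mode, the default) or accepts per-pixel delta rasters for users holding
real GCM fields; rainfall amounts and CV are clipped below at zero.
Deltas are additive for all variables, including rainfall, because the
source summary is printed as additive changes in mm. Summary rounding is
half away from zero (`round_half_up()`), since banker's rounding fails
printed half-way cells (+3 from 2.5, +1.7 from 1.65).

One data note: in the bundled table's published summary, four RCP8.5
model-mean cells (sowing-month rain, rainfall CV, growing-season rain,
Mar--Sep mean temperature) are inconsistent with the arithmetic mean of
their own per-model rows (13.75 vs 13.9, 2.5 vs 2.8, 17.25 vs 17.5,
2.35 vs 2.3). `summarize_deltas()` always recomputes means from the
per-model values; the acceptance tests assert the ten self-consistent
cells at printed precision and pin the other four to exact arithmetic.

## Multi-crop aggregation

Per-crop class maps are stacked three ways: per-pixel counts of crops at
each class level; the combined rank-sum score (4 = all four crops limited
up to 16 = all optimal); and pairwise rank sums (2--8) with unordered
category labels (`Ld-Ld` ... `Op-Op`). Area accounting defaults to an
equal-area cell of `(111.32 x 0.05)^2` km^2 (a 0.05-degree cell at the
equator) with a latitude-cosine mode for geographic grids; reported
changes are percentage points of national masked area alongside km^2, and
multi-GCM change tables average the per-GCM changes. In the pipeline, the
per-crop area-change tables use per-GCM projections (multi-model mean
change), while multi-crop maps under a scenario use the multi-model mean
delta, giving one future map per crop per scenario.

## The synthetic world

`generate_weather()` makes no attempt at stochastic-weather-generator
realism; it reproduces exactly the structural features the analysis
needs:

* a north/south phenology contrast — unimodal rainfall peaking around
  August (day-of-year 227, sd 45) north of the split latitude, bimodal
  with May/October peaks (135/280, sd 35) south of it;
* a calibrated climatology — base rate and seasonal amplitude are solved
  analytically so each zone's expected 1 Mar--30 Sep rainfall total
  equals 1246 mm (the national baseline), with 35% of seasonal rain from
  the aseasonal base; the diurnal range is 9.9 degC with 1 degC daily
  noise; mean temperature 25.5 degC with a 1.8 degC seasonal cycle and a
  1.5 degC latitudinal gradient (north warmer);
* spatial heterogeneity — independent smooth random surfaces (35%
  relative amplitude) modulate the rainfall base rate and seasonal
  amplitude separately, plus an independent 1 degC temperature surface
  and a soil-carbon surface around 30 t/ha. Because the surfaces are
  independent, derived predictors are correlated (they share the same
  daily rain) but not collinear.

Daily precipitation is `max(0, base + amplitude * kernel + noise)` with
Gaussian noise (sd 1.5 mm/day); truncation at zero introduces a small
positive bias that stays well inside the 10% calibration tolerance.
`generate_region()` partitions the grid into nearest-seed-pixel Voronoi
districts (contiguous-ish, every district non-empty), and
`generate_yields()` makes district yield a configured monotone response
of the district mean of one driving predictor plus interannual Gaussian
noise (default 0.25 t/ha against a roughly 2--6 t/ha yield range, so
district class flips are rare over an 11-year mean). All randomness
derives from one root seed through per-component streams, so adding a
component never perturbs another's draws. Grid spacing is 0.05 degrees,
mirroring the emulated precipitation product; temperatures are generated
at the same grid because coarser sources are resampled to match anyway.
Defaults: 11 years starting 2006.

What a green test does *not* establish: the generator has no dry-day
process, no spatial rainfall correlation beyond the smooth fields, no
interannual climate modes, and yields carry no technology trend or
management signal — so passing recovery tests demonstrate that the
pipeline machinery is correct, not that the approach would achieve any
particular skill on real national data (the published headline accuracies
depend on data that is not redistributable).

For parameter-recovery testing, `generate_recovery_samples()` uses a
direct design in which the class is a noisy monotone function of one
named driver and the other seven predictors are independent draws: the
latent expected yield is the response of the driver, cut at the quartiles
of its noise-free distribution, with Gaussian noise whose default sd
(0.188 t/ha) was calibrated once — before any classifier was run — so the
closed-form Bayes accuracy is approximately 0.85. This is the only
design with a computable Bayes rule, and it makes an exclusive
gain-share floor for the driver meaningful; in the full weather-to-yield
pipeline the rainfall predictors are inherently collinear, so there the
recovery tests assert accuracy/kappa and first-ranked importance, not an
exclusive share.

## Degenerate inputs and numerical choices

* Windows are validated per year against the data span; a window outside
  the span is an error, not a silent partial sum.
* `tmax < tmin` anywhere rejects the input.
* Fewer than 4 districts with finite mean yields cannot be quartered.
* Classifier training with a single class present is an error; grid-CV
  ties resolve to the first grid row.
* Kappa with `p_e = 1`, CV with zero rain, and per-class ratios with
  empty denominators follow the explicit conventions above.
* All file interchange is plain text (long-format CSV for grids, CSV for
  tables, JSON for the manifest); no binary geospatial formats are
  required at any stage, which keeps the pipeline dependency-light and
  the outputs diffable. Fitted models serialize to RDS.

## Known limitations

Suitability here is correlative, not agronomic: no evapotranspiration,
photoperiod or soil-water balance; no yield detrending or gap-filling; no
crop-interaction effects in the multi-crop scores (they are purely
additive ranks); no spatial cross-validation, so pixel-level accuracy
estimates are optimistic in the presence of spatial autocorrelation
(district-level labels shared by neighbouring pixels); and uniform
national deltas ignore within-country gradients of projected change
unless gridded deltas are supplied.
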