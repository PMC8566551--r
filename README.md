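# amphipheno

Predicting the onset of amphibian spring migration from plant phenology,
for road-mitigation planning.

Common toads (*Bufo bufo*) and common frogs (*Rana temporaria*) are
explosive breeders whose spring migration to spawning waters is
concentrated into a short window that shifts by weeks between years.
Temporary drift fences with buckets — the standard measure against
amphibian roadkill — only help if installed before the migration starts.
Because amphibian migration and early-spring plant phenology share the
same main driver (temperature, modulated by daylength), an
easy-to-observe plant phenophase such as goat willow or apricot flowering
can act as a field proxy for the imminent start of migration.

`amphipheno` turns that idea into a tested pipeline over citizen-science
sighting records:

1. **Detect migration events.** A sighting is part of a migration iff the
   individuals summed over its neighbourhood — conspecific records within
   a 1 km² disc (radius √(10⁶/π) ≈ 564.19 m, haversine) and within ±7
   days — reach 10. Records are banded into climatic regions by site mean
   annual temperature (alpine < 5 °C excluded; cool [5, 7); moderate
   [7, 9); warm ≥ 9 °C).
2. **Extract onsets.** Per (taxon, region, year): earliest flagged
   sighting day-of-year for amphibians (suppressed when fewer than 4
   flagged observations exist in the region-year), first report for
   plants.
3. **Describe.** Shapiro–Wilk normality, paired between-region shifts,
   Mann–Kendall trends (tie-corrected normal and exact permutation p),
   Pearson plant–amphibian correlations, all at α = 0.05.
4. **Model and forecast.** Robust MM-regression (95%-efficiency bisquare,
   S-estimate scale) of amphibian onset *y* on plant onset *d* plus a MAT
   covariate,

   *y* = β₀ + β₁ d + β₂ MAT + ε,

   validated by leave-one-out cross-validation against an intercept-only
   null, with Cook's distance (flag at 4/n) and VIF diagnostics. The lag
   forecast is *ŷ*(d) − d with a 95% CI of the conditional mean; it is
   affine in *d* with slope (β₁ − 1).

A synthetic-data generator (`sim_config()` / `simulate_dataset()`) with
known ground-truth onsets and lags makes the whole pipeline testable
without the original sighting databases, which are not public. See the
vignette in `vignettes/phenology-pipeline.Rmd` for the full methods
account.

## Worked example

```r
library(amphipheno)

report <- run_all(sim_config(seed = 7))
report
#> amphipheno pipeline report
#>   simulated: 3219 observation(s), 1197 phenology report(s)
#>   flagged as migration: 2043 record(s), 342 event(s)
#>   onset rows: 114 amphibian, 399 plant
#>   models (LOOCV RMSE, days):
#>     response    predictor slope rmse_loocv null_rmse_loocv adj_r2
#>  common_frog      apricot 0.966       1.47            8.16  0.980
#>  common_frog common_hazel 0.938       1.68            8.16  0.970
#>  common_frog  goat_willow 0.908       1.81            8.16  0.974
#>  ...
```

Reading the model table: for the common frog, apricot flowering predicts
migration onset with an out-of-sample error of 1.47 days, versus 8.16
days for the intercept-only null — knowing the plant date removes ~80% of
the forecast error. The slope near 1 means migration tracks flowering
almost day for day.

The lag lookup table for the best frog model answers the field question
directly — "apricot flowered today (day *d*); in how many days does
migration start?":

```r
report$lag_tables[["common_frog~apricot"]]
#>  plant_doy lag_days lag_days_int ci95_low_int ci95_high_int
#>         50     4.92            5            3             7
#>         60     4.58            5            4             6
#>         70     4.24            4            4             5
#>         80     3.90            4            3             4
#>         90     3.56            4            3             4
```

(Under this generator config the frog's true lag is tied to goat willow;
apricot flowers ~16 days later, so its lag is correspondingly shorter.)
Single fits are available directly:

```r
sd_tbl <- report$start_dates
tab <- model_table(sd_tbl[sd_tbl$taxon == "common_frog", ],
                   sd_tbl[sd_tbl$taxon == "goat_willow", ],
                   "common_frog", "goat_willow")
fit <- fit_robust(model_spec("common_frog", "goat_willow"), tab)
predict_onset(fit, plant_doy = 60, mat = "moderate")
```

An externally derived onset table (CSV with columns `taxon`, `region`,
`year`, `onset_doy`) can enter mid-pipeline, skipping simulation and
detection: `run_all(start_dates = "onsets.csv")`.

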