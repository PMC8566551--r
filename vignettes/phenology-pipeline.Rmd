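---
title: "Predicting amphibian spring migration from plant phenology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting amphibian spring migration from plant phenology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amphipheno)
```

## The problem

Common toads (*Bufo bufo*) and common frogs (*Rana temporaria*) are
explosive breeders: in early spring, large numbers migrate from
hibernation sites to spawning waters within a window of days. Where
roads cut these routes, temporary drift fences with buckets are the
standard mitigation — but they only work if installed *before* the
migration starts, and the start shifts by weeks from year to year.
Because both amphibian migration and early-spring plant phenology are
driven largely by temperature (and daylength), an easily observed plant
phenophase — goat willow or apricot flowering, say — can serve as a
field-observable proxy for the imminent onset of migration.

`amphipheno` implements that idea as a pipeline over citizen-science
sighting records:

1. **Detection** — classify individual amphibian sightings as migration
   events using spatial, temporal and quantitative criteria.
2. **Onset extraction** — reduce flagged sightings and plant phenophase
   reports to one onset day-of-year (DOY) per taxon, climatic region
   and year.
3. **Descriptive statistics** — normality, between-region shifts,
   Mann–Kendall temporal trends, Pearson plant–amphibian correlations.
4. **Robust regression** — MM-type linear models predicting amphibian
   onset from plant onset (plus a temperature covariate), validated by
   leave-one-out cross-validation against an intercept-only null, with
   lag forecasts and 95% confidence intervals.

A synthetic-data generator with known ground truth makes every stage
testable end to end without access to the original sighting databases,
which are not public.

## Migration detection

Presence-only sighting data cannot distinguish a migrating animal from
a dispersing one record by record. The pipeline uses an operational
definition: a sighting is part of a migration if the individuals summed
over its *spatiotemporal neighbourhood* reach 10. The neighbourhood of
an examined record contains every conspecific record within an area of
1&nbsp;km² around it and within 7 days (two-sided, inclusive, calendar-day
arithmetic) of its date, including the record itself — so a single
sighting of ten or more individuals always qualifies.

Two geometric readings of "within an area of 1 km²" are shipped:

* **disc** (default) — a disc of area 1 km² centred on the examined
  record, radius $r = \sqrt{10^6/\pi} \approx 564.19$ m. This follows
  the record-anchored phrasing of the criterion and makes flags
  translation-invariant.
* **grid** — records share a fixed 1 km × 1 km cell (pre-projected
  metric coordinates only), for sensitivity analysis.

Distances are great-circle (haversine) on WGS84 coordinates, or
Euclidean for pre-projected input. Species are processed in isolation:
toad records never contribute to frog neighbourhoods. The flag
predicate is monotone — adding records, growing the radius or window,
or lowering the threshold can only add flags — and the test suite
checks the implementation against a brute-force per-pair
reimplementation on hundreds of random tables.

The threshold is applied as *summed individuals ≥ 10* everywhere
(`min_individuals = 10`, configurable). Duplicate records (same
coordinates and date) are kept; deduplication is the data provider's
responsibility.

## Climatic regions and onset extraction

Each record carries its site's mean annual air temperature (MAT,
1971–2000 normal), which bands the study area into left-closed regions:
alpine (MAT &lt; 5 °C, excluded from analysis — little migration
occurs there), cool [5, 7), moderate [7, 9) and warm (≥ 9 °C).

For **amphibians**, the onset per (species, region, year) is the DOY of
the earliest flagged record, *provided* at least 4 flagged observations
exist in that region-year. With presence-only data a region-year with
very few migration records likely missed the true start entirely, so it
yields no row rather than a misleadingly late one. Ties on the earliest
day collapse to one onset; by default each flagged observation counts
toward the minimum (counting deduplicated events instead is a flag).
For **plants**, the onset is simply the first report per (species,
region, year); no minimum applies.

The onset table — one row per (taxon, region, year) — is the central
object of the analysis, and `read_start_dates()` doubles as the
mid-pipeline entry point for an externally derived onset table when raw
sightings are unavailable.

When an amphibian and a plant series are paired for modelling, rows are
inner-joined on (region, year) and pooled across regions, the warm
region included by default despite its sparse data (a region filter is
available). A region-level row has no single site, so the MAT covariate
is encoded as the region's band midpoint: cool 6, moderate 8, warm
10 °C (the warm band is open above; 10 °C is the midpoint of the 9–11 °C
span covering nearly all warm-region sites). A categorical region
encoding is available as an alternative.

## Statistical layer

All reports evaluate at α = 0.05, and **no multiple-testing correction
is applied** — the correlation table is descriptive, feeding predictor
selection, not a family of confirmatory claims.

* `pearson_correlation()` — two-tailed product-moment correlation, p
  from the t transform with n − 2 df.
* `mann_kendall()` — trend test with the standard tie-group variance
  correction and continuity-corrected normal z. Because onset series
  are short (≤ 19 years), an exact permutation p is reported alongside:
  by enumeration of the inversion-count distribution for tie-free
  series with n ≤ 10, by full enumeration for tied series with n ≤ 8.
  Both p values appear in pipeline reports.
* `paired_region_test()` — paired t on within-(taxon, year) differences
  between regions; a zero-variance difference vector is reported as an
  exact shift instead of a degenerate t.
* `shapiro_wilk()` — normality diagnostic only, never a gate.

Missing years inside a series are simply absent; no interpolation.

## Robust regression and lag forecasts

Citizen-science onset tables contain occasional gross errors (a
misdated report becomes an onset 30 days early), so the models are fit
with the MM estimator: a high-breakdown S-estimate of residual scale
followed by a redescending bisquare M-step tuned to 95% Gaussian
efficiency (c = 4.685), via `MASS::rlm(method = "MM")`. The S-stage
subsampling runs under a fixed documented seed (`20211103`), so fits
are exactly reproducible and do not disturb the caller's RNG stream.
Coefficient covariance is the robust sandwich form from `summary.rlm`.

Models take one or at most two plant predictors plus optionally MAT;
rank-deficient designs error naming the collinear columns. Diagnostics:

* `cooks_leverage()` — classical Cook's distance from the
  least-squares hat matrix of the same design, flagging rows with
  D &gt; 4/n for scrutiny (never auto-dropped). Unit weights are the
  default deliberately: weighting by the robust fit's final weights
  would hide exactly the influential points the diagnostic exists to
  surface (an option computes the weighted version).
* `vif()` — 1/(1 − R²) per right-hand-side variable, ∞ under perfect
  collinearity, flagged above 10.
* `loocv_rmse()` — n refits, each predicting its held-out row. In the
  least-squares limit (`engine = "ols"`) this reproduces the
  hat-matrix PRESS identity to machine precision, which the tests
  assert.
* `compare_to_null()` — the null is an intercept-only robust location
  fit, scored by the same LOOCV; its adjusted R² is 0 by construction.

`predict_onset()` turns a single-plant fit into the quantity a fence
crew needs: observe the plant phenophase on day $d$, then migration is
predicted $\hat{y}(d) - d$ days later. The 95% interval is the
**confidence interval of the conditional mean** (t quantile, n − p df),
not a prediction interval — the question is "when does the typical
migration start given this plant signal", and the CI of the mean is the
band on that climatological expectation; a prediction-interval mode is
available for single-year forecasts. The lag is affine in plant day
with slope (slope − 1): a plant slope of 0.75 means every 4 days of
later flowering close 1 day of lag. Integer summaries round half away
from zero; real values are retained. Forecasts more than 15 days
outside the fitted plant-DOY range carry an extrapolation warning.

Model selection is a report, not a search: candidate predictors are the
plants whose phase starts before the amphibian's migration on average
and correlates significantly with it; each is fit singly and compared
to the null by LOOCV RMSE, and the best model per species feeds the lag
lookup table (plant day 50–90 in steps of 5).

### Numerical choices

* **Exact interpolation.** When least squares already interpolates the
  data the S-scale is zero and IRLS cannot iterate; the fit degenerates
  to least squares, with zero covariance (CIs collapse to the point
  prediction).
* **Collapsed S-scale.** Onsets are integer days, so more than half the
  rows can lie *exactly* on one line; the S-scale then collapses to
  machine zero and the M-step weights degenerate. The residual
  deviations in that regime are rounding noise, not outliers, so the
  fit falls back to least squares (threshold: robust scale below
  10⁻⁶·(1 + sd(y))).
* A LOOCV fold whose refit fails is skipped with a warning and counted,
  never silently imputed.

## The synthetic-data generator

`sim_config()` / `simulate_dataset()` emulate the study system with
known ground truth. Defaults encode the study conditions; each value
below is a modelling choice stated once:

* **Years 2000–2018**; cool and moderate regions with 4 sites each,
  the warm region sparse (1 site) to mirror its thin real-world data.
* **Shared temperature driver** — one anomaly per region-year,
  N(0, 1.5 °C), acting on every taxon at −4 days/°C. This is the
  minimal structure that produces plant–amphibian correlation; it is
  chosen over a daily weather series because every downstream stage
  only consumes onsets.
* **Plant base onsets** (moderate region, DOY): snowdrop 35, common
  hazel 38, goat willow 58, apricot 74, European larch 88, horse
  chestnut 92, silver birch 95 — spanning winter flowering to spring
  leaf unfolding, in that phenological order. Regional stagger: cool
  +9 days, warm −2.
* **True lags** — amphibian true onset = reference plant (goat willow)
  true onset + lag + N(0, 1 day): common frog +21, common toad +23
  days. These are the generator's ground truth, recovered by the
  pipeline in tests.
* **Migration bursts** — per site, year and species: 4–8 sighting
  records, the first on the true onset day, the rest within 6 days
  after, individual counts 1 + Poisson(3) topped up so each burst sums
  to ≥ 10. Every burst passes the detection criteria by construction.
* **Background** — Poisson(20) scattered singletons per region-year,
  counts ≤ 3, uniform January–May, spread over a ~75 × 55 km box, so
  the quantitative criterion separates them cleanly from bursts.
* **Observer delay** — plant first reports lag the true onset by
  Exponential(mean 2 days): reports can only be late, never early.
  This makes "first report per region-year" a deliberately biased-late
  onset estimator; with 4 sites per region the expected bias of the
  regional minimum is ~0.5 days, and the recovered lag sits
  correspondingly ~0.5–1 day below the true 21 days. The tests
  quantify this bias rather than hide it.

The generator is deterministic: one seed, byte-identical CSVs.

**What it does not emulate** — and hence what passing tests do *not*
show about real data: per-project reporting-effort heterogeneity across
the four source platforms, roadkill/mortality processes, daily weather
(and thus within-season weather reversals), observer misidentification,
and spatial drift of observation effort across years. Parameter
recovery on this generator demonstrates the pipeline's correctness
under its stated model, not the ecological validity of any particular
real-world fit.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(seed = 7)
report <- run_all(cfg)
report$models            # candidate models, LOOCV RMSE vs null
report$lag_tables        # lag + 95% CI for plant DOY 50-90
```

Problem sizes throughout the examples and tests — 19-year series, 2–3
regions, a few thousand records, ≤ 60 region-year rows per model — are
the sizes this study design actually produces; the detection stage
handles tables of a few thousand records in seconds via a dense
pairwise distance matrix per species.

## Known limitations

* The onset estimator (earliest flagged record / first report) is
  biased late by under-observation and has no correction; the bias is
  quantified on synthetic data instead.
* MAT as a region-band midpoint discards within-region site variation;
  users with per-site temperature normals can model at finer grain by
  supplying their own paired table.
* The warm region rarely supports its own model (few rows); pooled
  models dominated by cool/moderate rows should be extrapolated to warm
  sites with care.
* Detection counts are sensitive to coordinate precision: records
  snapped to a grid coarser than ~500 m make the disc criterion
  unreliable.
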