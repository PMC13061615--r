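# spatcog

Spatial mapping of air-pollution–cognition interactions on urban
kilometre grids.

Urban cohort studies often record an outcome (for example reaction time in a
cognitive test), exposure estimates (NO₂, NOₓ, PM₂.₅ from land-use
regression), a set of confounders, and a residential location geocoded to a
1 km² grid cell. Conventional regression collapses the spatial dimension and
can dilute or miss associations that are concentrated in particular places.
`spatcog` implements a mass-univariate spatial alternative for
epidemiologists and public-health analysts: it maps *where* an
exposure–outcome interaction is statistically credible, with family-wise
error control over the whole map, and summarises each significant region in
an interpretable sign vocabulary.

## The method

**Response.** Each participant *i* contributes a *sample concentration* map:
an isotropic Gaussian density centred at their home cell,
`y_i(v) = N(c_v; c_i, σ²I)` evaluated at every cell centre `c_v`. The kernel
sd is set by a containment rule — by default 95% of the kernel mass inside a
5 km diameter, giving `σ = 2500 / sqrt(−2 log 0.05) ≈ 1021 m` from the
Rayleigh CDF.

**Model.** At every grid cell `v` the same global design is regressed onto
the local response by OLS:

    y(v) = Xβ(v) + ε(v),   X = [1, confounders, pollution, cognition,
                                cognition × confounders, cognition × pollution]

yielding coefficient maps `β̂_j(v)`, residual variance `σ̂²(v)` with
`ν = N − P` degrees of freedom, and t-maps
`t_j(v) = β̂_j(v) / sqrt(σ̂²(v) [(XᵀX)⁻¹]_jj)`.

**Inference.** The interaction t-map is thresholded at voxel-level
family-wise error `α = 0.05`, two-tailed, using Gaussian random field
theory: `P(max |t| > u)` is approximated by the expected Euler
characteristic `Σ_d R_d ρ_d(u)` with resel counts `R_d` from the residual
smoothness (FWHM) and the Student-t EC densities `ρ_d`. The working
threshold is the smaller of the random-field and Bonferroni solutions.

**Interpretation.** Suprathreshold cells are grouped into sign-coherent
connected regions, regions with fewer than 10 participants are dropped, and
each region is classified from the median signs of its interaction,
cognition and pollution coefficient maps: `consistent_rising` (+,+,+, e.g.
above-average pollution with slower cognition), `consistent_falling`
(+,−,−), `crossed` (negative interaction with opposed individual effects),
or `inconsistent`.

A non-spatial comparator — Bayesian multiple regression with a ridge prior
(`β | σ², τ² ~ N(0, σ²τ²I)`, Jeffreys prior on σ², half-Cauchy on τ) fitted
by a compiled Gibbs sampler — reports posterior mean, sd, 95% CI,
t statistic, rank, effective sample size, R², and two-tier sign flags
(`**`: 95% CI excludes zero; `*`: interquartile range does).

A synthetic-cohort generator produces grid-snapped cohorts with uneven
spatial density, correlated confounders, exposure fields with road-like
ridges, and an optional interaction effect planted in a known disk of
cells, so every claim above can be checked against ground truth.

## Worked example

```r
library(spatcog)

grid <- grid_spec(n_cols = 26, n_rows = 26)          # 26 x 26 km at 1 km
sim <- generate_cohort(
  grid, n = 15000,
  interaction_disk = list(easting = 13000, northing = 13000, radius = 3000),
  interaction_coef = 0.5, seed = 2026
)
confounders <- c(paste0("conf_", sprintf("%02d", 1:10)), "sex")
cohort <- preprocess_cohort(
  sim$cohort,
  continuous = c(paste0("conf_", sprintf("%02d", 1:10)), "no2", "nox", "pm25"),
  cognition  = c("reaction_time", "completion_time")
)
fit <- fit_spatial_interaction(
  cohort, grid,
  cognition = "reaction_time", pollution = "no2",
  confounders = confounders
)
fit
#> <spatcog_fit> reaction_time x no2: n = 11431, P = 26, df = 11405
#>   FWHM (2.61, 2.63) cells, t* = 3.965 (bonferroni), 75 significant cell(s) in 3 region(s)
#> # A tibble: 3 × 4
#>   region_id n_cells n_participants classification
#>       <int>   <int>          <int> <chr>
#> 1         1      24            599 crossed
#> 2         2      22           1020 consistent_rising
#> 3         3      29           1160 crossed
```

The preprocessing step trims missing and extreme rows (1st/99th percentile
per variable) and reports the counts; here 11,431 of 15,000 participants
remain. The fit prints the residual smoothness in cells, the family-wise
threshold `t* = 3.965` (the Bonferroni solution was smaller than the
random-field one at this smoothness) and the retained regions. Region 2 is
the planted disk: positive interaction with positive individual effects —
above-average NO₂ co-occurring with slower reaction times. The two
`crossed` regions are the compensatory negative-interaction zones that a
localized positive interaction necessarily induces elsewhere (see the
vignette). Recovery against the ground truth:

```r
overlap_report(sim$truth, fit$mask & fit$effect_maps[1, ] > 0)
#> # A tibble: 1 × 6
#>   n_truth n_detected n_overlap  dice jaccard hit
#> 1      32         22        22 0.815   0.688 TRUE
```

`tidy(fit)` returns the full region table (coefficient quantiles per
region), `glance(fit)` the one-row model summary, and `autoplot(fit)` the
t-map with region outlines. The non-spatial comparator:

```r
ridge <- bayes_ridge(cohort, response = "reaction_time",
                     predictors = c(confounders, "no2"),
                     config = chain_config(seed = 1))
glance(ridge)
#> # A tibble: 1 × 6
#>       n     p n_draws    r2 n_flag_strong n_flag_weak
#> 1 11431    12    4000 0.151            12           0
```

`run_pipeline()` drives the whole analysis (all cognition × pollution
combinations) from a cohort CSV and a config list, writing coefficient and
t-map rasters (ESRI ASCII grid), threshold and region reports (JSON,
GeoJSON), comparator tables (CSV) and a structured run log.
`run_sensitivity_suite()` repeats the analysis over kernel sizes, an
expanded window, a translated window and the non-mover subcohort, and
reports mask overlap against the base run.

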