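---
title: "Mapping exposure-cognition interactions on urban grids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping exposure-cognition interactions on urban grids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatcog)
```

This vignette is the package's own account of the statistical machinery it
implements: the model and its assumptions, the parameters that matter and
their defaults, what the synthetic cohort generator does and does not
emulate, the numerical conventions, and the design choices made where more
than one reasonable option existed. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The model

### Sample concentration as the response

Point cohorts are made amenable to image-style mass-univariate regression
by giving each participant a *sample concentration* map: a unit-mass
isotropic Gaussian density centred at the participant's home cell,
evaluated at every cell centre of the analysis grid. At any location, the
response across participants is an indicator of how close each participant
lives to that location. Stacked over $N$ participants and $C$ cells this is
the $N \times C$ response matrix $Y$.

The kernel is parameterized by *containment* rather than by its sd: the
fraction $f$ of kernel mass inside a stated diameter $d$. For an isotropic
2-D Gaussian the mass inside radius $r$ is the Rayleigh CDF
$1 - e^{-r^2/2\sigma^2}$, so

$$\sigma = \frac{d/2}{\sqrt{-2\log(1-f)}},$$

and the default (95% within 5 km) gives $\sigma \approx 1021$ m, i.e. an
effective field smoothness of $2.355\,\sigma \approx 2.4$ cells on a 1 km
grid. `kernel_containment_pct()` verifies the rule by numerical
integration. Rows of the response stack are *not* renormalized: every
per-cell t statistic is invariant to any rescaling of a cell's response
shared across participants, a property the test suite asserts directly, so
the mass convention is inconsequential. For speed the kernel is truncated
beyond $6\sigma$, where the neglected mass is below $10^{-8}$.

### The shared design

One global design matrix serves all cells:

$$X = [\,1,\ \text{confounders},\ \text{pollution},\ \text{cognition},\
       \text{cognition}\times\text{confounders},\
       \text{cognition}\times\text{pollution}\,].$$

With 11 confounders this is $P = 26$ columns. Interaction columns are raw
products of the already-standardized factors and are deliberately not
re-standardized, so that regional sign summaries read directly off the
coefficient maps. Variables arrive prepared by `preprocess_cohort()`:

* rows with missing values, or with any named continuous variable strictly
  outside its 1st–99th percentile, are removed. Percentiles use linear
  interpolation between order statistics (`quantile()` type 7) and are
  computed per variable on the input table, with the intersection of the
  per-variable keeps retained (each of $k$ trimmed variables removes up to
  2%, so the joint reduction can approach $2k$% when extremes do not
  overlap). Trimming is a single-pass contract: re-running recomputes
  percentiles and may trim further.
* continuous covariates are standardized to mean 0, sample sd 1 (binary
  covariates are left untouched);
* outcome times are mapped through ordered quantile normalization,
  $\Phi^{-1}((\mathrm{rank}-1/2)/n)$ with average ranks for ties; an
  all-tied input degrades to zeros rather than failing.

### Voxelwise OLS and t-maps

At every cell, ordinary least squares against the shared design:
$\hat\beta(v) = (X^\top X)^{-1}X^\top y(v)$,
$\hat\sigma^2(v) = \mathrm{RSS}(v)/\nu$ with $\nu = N - P$, and

$$t_j(v) = \frac{\hat\beta_j(v)}{\sqrt{\hat\sigma^2(v)\,[(X^\top X)^{-1}]_{jj}}}.$$

The design is QR-factorized once and shared across cells. Cells with zero
residual variance (possible where the truncated kernel leaves a cell with
identically zero response — remote corners of a window with a clustered
cohort) get $t = 0$ and a degeneracy flag; flagged cells can never become
significant.

## Family-wise error control

The interaction t-map is thresholded at voxel-level family-wise error
$\alpha$ (default 0.05, two-tailed). Random field theory approximates the
exceedance probability of the field maximum by the expected Euler
characteristic of the excursion set,

$$P\!\left(\max_v t(v) > u\right) \approx \sum_{d=0}^{2} R_d\,\rho_d(u),$$

with the Student-t EC densities $\rho_d$ (order 0 the upper-tail t
probability; orders 1 and 2 the standard closed forms implemented in
`ec_density_t()`) and resel counts $R_d$ measuring the search region in
units of the field's smoothness.

**Smoothness.** The FWHM per axis is estimated from the spatial roughness
of the residual stack: residuals are normalized to unit sum of squares per
cell, and the mean squared forward difference along an axis estimates the
variance $\lambda$ of the field's derivative, giving
$\mathrm{FWHM} = \sqrt{4\log 2/\lambda}$. Cell pairs involving a
zero-variance cell are excluded from the average. Because smoothing is
imposed by construction here, the analytic value
$2.355\,\sigma/\text{cell size}$ is available as a cross-check
(`kernel_smoothness()`); the two routes agree to within a lattice
discretization bias of a few percent, which the test suite bounds.

**Resels.** For the full rectangular window of $n_x \times n_y$ cells:
$R_0 = 1$, $R_1 = n_x/f_x + n_y/f_y$, $R_2 = n_x n_y/(f_x f_y)$. This cell-
count convention (a unit-FWHM 26×26 window has $R_2 = 676$) is marginally
more conservative than conventions based on $n-1$ spans.

**Threshold.** `fwe_threshold()` solves $\sum_d R_d\rho_d(t) = \alpha/2$
(two-tailed, applied to $|t|$ by symmetry) by root finding on $(0, 100)$ to
tolerance $10^{-8}$, and returns the smaller of that solution and the
Bonferroni quantile $t_{1-\alpha/(2C)}$ over the $C$ cells — the standard
guard: Bonferroni is valid at any smoothness and prevents the random-field
solution from blowing up when the field is rough; the random-field solution
takes over when spatial correlation makes Bonferroni needlessly strict. The
two-tailed test is implemented as a single symmetric $|t|$ threshold at
$\alpha/2$ per tail, the stricter of the readings of "two-tailed" at the
map level. A cell exactly at threshold is included.

**What the control assumes.** The Euler-characteristic argument treats the
t-map as a smooth t-field, which holds asymptotically in $N$. The response
here is spiky — a participant's kernel contributes appreciably only within
a few cells — and interaction regressors are products of covariates with
kurtosis well above Gaussian, so at each cell the effective sample behind
the extreme tail is roughly $N \cdot 4\pi\sigma^2/A$ (a few dozen when
$N = 2000$ on a 676 km² window, several hundred at cohort sizes in the
tens of thousands). The package's null-simulation harness
(`simulate_null_fwe()`) measures the resulting operating characteristic:
with Gaussian covariate contrasts the control is strict at all sizes
tested, while for product-column (interaction) contrasts the realized
family-wise error exceeds the nominal level at $N = 2000$ and tightens to
strict control as $N$ grows toward realistic urban cohort sizes. This is a
genuine small-sample property of mass-univariate concentration regression,
not a thresholding artefact: the per-cell t marginal itself is
heavy-tailed at small $N$ (verifiable with a plain `lm()` at one cell), so
no map-level threshold rule can repair it.

## Significant regions and their interpretation

Suprathreshold cells are grouped into connected components
(8-connectivity by default; 4 available), with one deliberate refinement:
components are labelled separately within the positive and the negative
interaction excursion sets, so every reported region carries a definite
interaction sign. A raw $|t|$-mask labelling can merge abutting
opposite-signed excursions into one region whose median interaction is
near zero and whose interpretation is incoherent; sign-splitting removes
that failure mode while leaving the union of regions equal to the mask.
Regions with fewer than 10 participants (home cell inside the region) are
omitted; a region with exactly 10 is retained.

Each region is summarized by the (min, q25, median, q75, max) of the
interaction, cognition and pollution coefficient maps over its cells, and
classified by the median signs $(s_I, s_C, s_P)$:

| $s_I$ | $s_C$ | $s_P$ | classification |
|---|---|---|---|
| + | + | + | `consistent_rising` |
| + | − | − | `consistent_falling` |
| − | +/− | −/+ | `crossed` |
| anything else | | | `inconsistent` |

With response-time outcomes, `consistent_rising` reads as above-average
exposure co-occurring with slower responses, and `consistent_falling` as
below-average exposure with faster responses. A median within $10^{-12}$
of zero is treated as sign-degenerate and classified `inconsistent`
(conservative). `subregion_diagnostic()` re-classifies a region's
4-connected sub-components in isolation, for the case where an
`inconsistent` region is really two internally consistent neighbours.

**Compensatory excursions.** A genuinely localized positive interaction
necessarily induces negative interaction coefficients over the remaining
populated area: the voxelwise regression reads concentration contrasts
against the cohort mean of the product column, so participants carrying
the elevated product lower the fit where they are absent. The induced
amplitude scales with the cohort fraction inside the true region. In
recovery experiments these compensatory regions are true features of the
generating model, which is why `planted_recovery()` scores overlap against
the sign-matching excursion and reports the two-tailed overlap alongside.

## The Bayesian ridge comparator

The non-spatial benchmark is Bayesian multiple regression with a ridge
prior, fitted by Gibbs sampling (compiled core):

$$y = \alpha + X\beta + \varepsilon,\quad
  \varepsilon \sim N(0, \sigma^2 I),\quad
  \beta \mid \sigma^2, \tau^2 \sim N(0, \sigma^2\tau^2 I),$$

with a flat prior on $\alpha$, Jeffreys prior on $\sigma^2$, and a
half-Cauchy prior on $\tau$ implemented as an inverse-gamma scale mixture.
Full conditionals are updated in the order
$(\beta, \sigma^2, \tau^2, \text{mixing variable})$. Fixing $\tau^2$ to a
large value recovers OLS (the conjugate-limit anchor asserted in the
tests); fixing it small shrinks monotonically toward zero.

Chain defaults are desk-scale — 2,000 burn-in, 4,000 retained — which at
$P \approx 12$ gives posterior means with Monte-Carlo error well below the
posterior sds; `paper_chain_config()` provides the heavyweight schedule
(100,000 burn-in, 20,000 retained, plus a further 100,000 thinned by 5)
for production tables. Summaries per predictor: posterior mean, sd,
equal-tailed 95% credible interval (2.5/97.5 percentiles of draws),
interquartile range, $t = \text{mean}/\text{sd}$, 1-based rank of $|t|$
among the model's predictors (ties broken by column order), and effective
sample size by Geyer's initial monotone positive-sequence estimator,
capped at the chain length. ESS is reported both raw and per 100 retained
draws, since reporting conventions differ and the package takes no stance
on which a given table uses. Flags: `**` when the 95% interval excludes
zero, `*` when only the interquartile range does.

One calibration subtlety: under a global null the half-Cauchy ridge
shrinks all coefficients by an equilibrium factor that is essentially
independent of $n$ (the posterior for $\tau^2$ tracks $\beta^\top\beta$,
which itself scales with the shrinkage), so null $|t|$ statistics are
damped by a constant factor rather than driven to zero. The strong `**`
tier is then clean under the null, while the interquartile `*` tier can
still trip on individual null draws — the test suite asserts exactly that,
together with 95%-interval coverage of true coefficients between 92% and
98% across repeated synthetic fits.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with all
randomness flowing from one seed:

* **Locations**: a mixture of four isotropic Gaussians truncated to the
  window (weights 0.35/0.25/0.22/0.18, sds 9–13% of the window extent, one
  centre at the window centre), snapped to cell centres — an unevenly
  clustered urban cohort at 1 km resolution.
* **Exposures**: one latent field per cohort — smoothed Gaussian noise
  (4 km length scale) plus two road-like ridges through the centre
  (800 m width) — read at the home cell, plus covariate noise calibrated
  so the three exposure covariates correlate at 0.8 by default, mimicking
  the strong mutual correlation of co-emitted pollutants.
* **Confounders**: ten continuous covariates with exchangeable correlation
  0.2 through a shared factor, plus a Bernoulli(0.5) binary left
  unstandardized downstream.
* **Outcomes**: two positive "times", affine images
  ($550 + 100\eta$ ms and $350 + 70\eta$) of standardized latents
  $\eta = \sum_j \beta_j x_j + c\,\mathrm{pol}^{(z)}\,\mathbf{1}_{\text{disk}} + \epsilon$.
  The affine constants are recorded in the ground truth so closed-form
  OLS recovery checks can invert them exactly. Default main effects are
  moderate (0.05–0.3 sd); the planted interaction defaults to $c = 0.5$
  sd per exposure sd inside a disk of cells. Centring the disk indicator
  would only move a constant multiple of the exposure into its main
  effect, so the plain inside-disk indicator is used.
* **Non-movers**: 75% of participants by default, matching a typical
  quarter-of-the-cohort address-change rate.

What it does *not* emulate: real covariate marginals or their skew,
spatially structured confounding (confounders are spatially unstructured
by construction), measurement error in outcomes, geodetic coordinates, or
within-city heterogeneity of exposure–confounder relationships. Passing
recovery tests therefore demonstrates that the machinery detects and
classifies what it models — not that real urban data meet the model's
assumptions.

## Sensitivity suite

`run_sensitivity_suite()` re-runs the full analysis per variant: kernel
containment diameters 1.25–10 km in 1.25 km steps, a window expanded by
5 km on each side, a window translated 8 km north-east, and the non-mover
subcohort. Variants are compared with the base run by the Dice coefficient
of the significance masks on the intersection of the windows; empty-versus-
empty masks count as 1 and empty-versus-nonempty as 0. A variant with an
empty cohort, or whose fit fails, is skipped with a log entry rather than
aborting the suite. Trimming percentiles are re-estimated per variant
cohort, since the cohort changes with the window.

## Numerical conventions, in one place

* Cells are half-open: a point on a shared boundary belongs to its
  east/north cell; the grid's east/north edge is out of bounds.
* Cell ids are row-major from the south-west corner; ASCII-grid rasters
  are written north-up (first file row = northernmost grid row) with 17
  significant digits, so write/read round-trips are bit-exact.
* Kernel truncation at $6\sigma$; threshold root-finding tolerance
  $10^{-8}$; degenerate cells flagged, never significant.
* Region numbering is raster-scan order of each component's first cell;
  `|t| = t^*` is included in the mask; `n_participants = 10` survives the
  filter.
* Rank ties break by column order; a zero median (within $10^{-12}$)
  classifies `inconsistent`.
* Seeds: every stochastic entry point takes one integer seed; sub-streams
  derive from it deterministically and the ambient RNG state is restored.

## Validation problem sizes

The operating-characteristic checks in the test suite run at sizes chosen
to make the Monte-Carlo error small relative to the tolerance being
asserted while keeping a full run of the suite in the minutes range:
200 global-null replicates at $n = 2000$; 20 planted-disk recoveries at
$n = 15{,}000$ (disk radius 3 km, effect 0.5 sd); 100 ridge fits at
$n = 2000$, $P = 12$ for interval coverage; 2,000 simulated t-fields
(FWHM 2.4 cells, 175 df, 3× oversampled lattice) for the
expected-Euler-characteristic calibration, probed where the predicted
exceedance is 0.02–0.10; and 500 replicates for the per-cell Student-t
null distribution check. The t-field lattice is oversampled because the
Euler-characteristic formula approximates the continuum maximum, which a
1-cell lattice systematically under-samples at FWHM 2.4.

## Known limitations

* Family-wise error control for interaction (product-column) contrasts is
  asymptotic in cohort size; see the discussion above. At a few thousand
  participants the realized rate exceeds the nominal level.
* Smoothness is assumed stationary; a single FWHM pair feeds the resel
  counts. Strongly nonstationary cohort densities violate this quietly.
* Cluster-extent and peak-level inference are out of scope; only
  voxel-level correction is implemented.
* The comparator implements the ridge prior only — no lasso/horseshoe —
  and model selection is out of scope.
* Rasters are planar ESRI ASCII grids; no geodetic CRS handling.
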