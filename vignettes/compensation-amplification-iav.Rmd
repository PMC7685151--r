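---
title: "Seasonal compensation and amplification in land-carbon flux IAV: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal compensation and amplification in land-carbon flux IAV: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carboniav)
library(dplyr)
```

## The scientific problem

Interannual variability (IAV) in gross primary production (GPP) and net
ecosystem exchange (NEE) can arise in two qualitatively different ways
within a growing season. Anomalies may be *coherent* across spring and
summer — a warm-dry or cool-wet year enhances or suppresses fluxes all
season long, **amplifying** the annual anomaly. Or they may *see-saw* — a
warm spring advances the seasonal cycle, so extra spring uptake is paid
back by a summer deficit, **compensating** within the season and muting the
annual anomaly. Arid, moisture-limited regions (such as western temperate
North America) tend to the first regime; mesic, energy-limited regions
(such as the eastern half) tend to the second. Which regime dominates
decides how much a region contributes to continental-scale IAV relative to
its mean productivity.

`carboniav` implements the full analysis chain that separates these
regimes in gridded monthly flux products: anomaly construction, the
compensation/amplification decomposition and its RATIO statistic, SVD mode
extraction, flux–climate attribution, and regional contribution summaries —
together with a synthetic-data generator that encodes the generative
structure the analysis assumes, so every stage can be validated end to end
as a parameter-recovery experiment.

Throughout, NEE uses the atmospheric sign convention (positive = flux from
land to atmosphere), fluxes are intensive (gC m⁻² month⁻¹) on regular
latitude–longitude grids, spring is April–June (AMJ), summer July–September
(JAS), and the growing season April–September.

## Anomalies

For each grid cell, the anomaly of a monthly series is the value minus the
per-calendar-month mean over a **baseline period** (at least two
contributing years per cell-month; missing values are never interpolated).
Optionally a linear trend is removed.

A single pass — climatology removal followed by one OLS line against
fractional time — leaves a residual that is neither mean-zero per month nor
trend-free: removing the line re-introduces small calendar-month structure
and vice versa. `compute_anomalies(detrend = TRUE)` therefore *alternates*
the two projections to convergence (backfitting), which is exactly the
joint least-squares projection out of the seasonal-cycle and linear
subspaces. Consequences worth knowing:

* a series that is exactly a repeated 12-month cycle plus a linear ramp
  detrends to zero (to rounding);
* both invariants hold simultaneously: per-calendar-month baseline means of
  anomalies are zero to 1e-10, and the OLS slope of the detrended series is
  zero to 1e-10;
* on complete, balanced records the result coincides with either
  single-pass order; the orders differ only under missingness or partial
  baselines, which is why the joint projection is the defensible default.

The baseline is an explicit argument everywhere because short records make
results period-sensitive; the test suite includes a baseline-shift
robustness check (a ±2-year shift on a stationary synthetic record moves
the downstream RATIO by well under 0.1 on average).

## The compensation/amplification decomposition

For each year *y* with a complete April–September record, with
$\Delta F_{\text{AMJ},y}$ and $\Delta F_{\text{JAS},y}$ the spring and
summer mean anomalies:

$$\text{comp}_y = \Delta F_{\text{JAS},y} - \Delta F_{\text{AMJ},y},
\qquad
\text{amp}_y = \Delta F_{\text{JAS},y} + \Delta F_{\text{AMJ},y}.$$

These satisfy $\text{comp}+\text{amp} = 2\,\Delta F_{\text{JAS}}$ and
$\text{amp}-\text{comp} = 2\,\Delta F_{\text{AMJ}}$ (to one floating-point
rounding). For NEE, $\text{amp}_y > 0$ means enhanced emission to the
atmosphere across the season. The multi-year summary is

$$\text{RATIO} = \frac{\sum_y |\text{comp}_y|}{\sum_y |\text{amp}_y|},$$

dimensionless and scale-free: above one, seasonal compensation dominates
IAV; below one, amplification dominates. Incomplete years are excluded from
*both* sums so numerator and denominator always cover the same year set,
and the year set is a required argument (period choice changes the metric —
the model-versus-observation table recomputes every dataset over both its
full period and any common sub-period for that reason). When
$\sum_y|\text{amp}_y| = 0$ the metric diverges; such cells are reported
with an `Inf` sentinel and a `degenerate` flag, never dropped silently,
because near-zero amplification genuinely produces very large values.

For i.i.d. centered Gaussian components the RATIO estimates the ratio of
the component scales, $\sigma_c/\sigma_a$ (both numerator and denominator
are means of half-normal variables); the acceptance suite verifies this to
2% at 10,000 synthetic years.

## SVD modes

Regional monthly anomalies are arranged into a 12 × n-years matrix (rows
January–December; years missing any month are dropped — no imputation) and
decomposed by thin SVD. The variance fraction of mode *i* is
$R^2_i = s_i^2 / \sum_j s_j^2$. No centering or standardization is applied
before the decomposition — anomalies are near-zero-mean by construction —
but a `center` flag exists. All 12 months enter by default (the mode
shapes are most interpretable over the full year); a window restriction can
be imposed upstream by masking months before aggregation.

Because singular-vector signs are arbitrary, each monthly vector is
oriented so its April–June mean is non-negative (ties broken on the
July–September mean), with year loadings flipped in step; this makes plots
and tests reproducible. Modes are labelled by seasonal shape: with *a* the
AMJ mean and *b* the JAS mean of the unit-norm vector, a mode is
`"amplification"` if $ab > 0$ and $\min(|a|,|b|) > \theta$,
`"compensation"` if $ab < 0$ with the same magnitude condition, and
`"other"` otherwise. The threshold $\theta = 0.05$ (about 1/13 of the
r.m.s. monthly weight) suppresses labels driven by near-zero season means;
it is a display/classification knob, not part of the decomposition.

## Driver attribution

Two protocols, both on yearly window statistics over common years:

* **Windowed correlation maps** (`windowed_correlation`): per cell, Pearson
  *r* between yearly flux-window means and driver-window means, a
  two-sided p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$, and a
  significance flag at α = 0.05. The lagged pairing — July–September flux
  against April–September driver — captures delayed effects of spring
  climate on summer fluxes; contemporaneous pairings use matching windows.
  Deliberately *no* autocorrelation correction (years are treated as
  exchangeable) and *no* multiple-testing correction across cells: the
  product is a per-cell significance stipple, and its type-I error is
  calibrated in the acceptance suite (rejection rate 0.05 ± 0.01 under the
  null at n = 17).
* **Sensitivity regressions** (`sensitivity_regression`): OLS of yearly
  April–September regional flux anomaly *totals* (window mean × 6 months,
  PgC per season) on regional driver anomaly *means* (area-weighted), so
  slopes come out in PgC K⁻¹ or PgC (m³ m⁻³)⁻¹. The fitted object wraps
  `stats::lm`; `glance()` returns slope, R², p and the slope's standard
  error.

## Grids, areas, regridding, regions

Cells are spherical quadrilaterals on a sphere of radius 6371 km, with
coordinates at cell centers and overlap computed on half-open edge
intervals (no double counting). The default analysis grid is 4° × 5° (lat
centers −88…88, lon centers −177.5…177.5), configurable. Regridding of
intensive fields is first-order conservative: each target cell is the
overlap-area-weighted mean of its source cells, with missing sources
excluded from the weight sum and target cells below a covered-area
fraction of `min_coverage = 0.5` (configurable) reported missing. A
complete field's global area-weighted mean is preserved to 1e-10 when the
target tiles the same domain; uniform fields are preserved to rounding at
any resolution. Longitude wrap-around across the antimeridian is not
handled inside a single regrid call; inputs are normalized to \[−180, 180)
on read.

Region masks carry fractional weights in \[0, 1\]. The default west/east
pair covers 24–52°N, 125–65°W, split at 103°W; cells straddling a boundary
receive their area-overlap fraction in each mask, so the pair tiles the
domain without double counting. The split meridian approximates the
arid/mesic divide and exists only as a drawn boundary in published maps,
so it is configurable and should be treated as an analysis choice.
Regional totals convert gC to PgC (× 10⁻¹⁵); regional driver series use
area-weighted means. Months with partial coverage record their covered
fraction; all-missing months are flagged missing, never silently zero.

## The synthetic generator

`generate_dataset()` simulates the statistical structure the analysis
assumes — not weather. For a cell in region *r*, year *y*, month *m*:

$$F(m) = \text{clim}(m) + \beta t + a_y\,u_{\text{amp}}(m)
       + c_y\,u_{\text{comp}}(m) + \varepsilon,$$

with unit-norm shapes $u_{\text{amp}}$ (half-sine over April–September)
and $u_{\text{comp}}$ (+1 April–June, −1 July–September, normalized —
its April–September sum is exactly zero), and year effects

$$a_y = \gamma_T\,\Delta T_y + \gamma_M\,\Delta M_y + \eta_a,
\qquad c_y = \kappa\,\Delta T_y + \eta_c,$$

where $(\Delta T_y, \Delta M_y)$ are jointly normal with correlation
$\rho_{TM}$ (default −0.77, the strong warm-dry coupling of arid regions)
and scales $\sigma_T = 1$ K, $\sigma_M = 0.02$ m³ m⁻³. Driver fields are
their climatologies plus the year effect plus small monthly weather noise
(0.1 K, 0.002 m³ m⁻³). NEE is generated as $-\lambda$ times the GPP
anomaly structure (default λ = 0.5 — a documented knob, since no
generative NEE model is given by theory) plus its own observation noise,
on a net-uptake climatology $-\,\text{nee\_frac}\times$ GPP climatology.

Sign conventions deserve a note: with the compensation shape oriented
positive-in-spring, a *positive* spring-temperature coupling κ on the GPP
side makes warm springs advance uptake (positive spring GPP anomaly,
negative summer); NEE inherits the opposite sign through −λ. An NEE-side
parameterisation would flip κ's sign; the package fixes the GPP-side
convention.

All randomness flows from one seed: regional year effects are drawn first
from the top-level stream, then each cell's observation noise comes from a
counter-derived substream, so enlarging the grid cannot reorder the
regional draws; output is bitwise-reproducible.

Presets encode the two regimes under study. `"west-like"`: σ of the
compensation side about 0.2 of the amplification side, moisture-coupled
(γ_M = 150 gC m⁻² month⁻¹ per m³ m⁻³, γ_T = −2 per K), small seasonal
cycle (G = 50). `"east-like"`: compensation-to-amplification scale about
5, spring-temperature-driven (κ = 6 per K), large cycle. `"two-region"`
places both on one grid and *solves* the eastern climatology amplitude and
NEE uptake fraction so the east/west April–September mean totals are
7.6× (GPP) and 3.5× (NEE) — the productive-east/variable-west
configuration — given the default grid's region areas and the straddling
cells' cross-mask weights. These magnitudes were fixed once, at
construction, as the study conditions.

What the generator does **not** emulate: spatial autocorrelation of
weather within a region beyond the fully coherent year effect (all cells
in a region share one $a_y, c_y, \Delta T_y, \Delta M_y$), realistic
respiration dynamics, specific historical years, trends in the drivers, or
non-Gaussian extremes. Passing tests therefore demonstrate that the
*method* recovers a known generative structure under realistic noise — not
that any particular real-world product has that structure.

## Numerical choices and degenerate inputs

* Earth radius 6371 km; pole-crossing cells clipped at ±90°.
* "Exact" algebraic identities (component identities, RATIO scale
  invariance, uniform-field preservation) hold to double rounding and are
  asserted at 1e-12–1e-14.
* Degenerate inputs: all-zero month-by-year matrices are flagged (variance
  fractions `NA`), zero-amplification cells carry the `Inf` sentinel,
  zero-variance driver series are a contract error, cells or months with
  insufficient data propagate `NA` rather than fabricating values.
* Monte-Carlo problem sizes are chosen to make the checks sharp at desk
  scale: 1,000 random series for the invariance sweep, 10,000 synthetic
  years for the half-normal limit, a 10,000-cell null grid for type-I
  calibration, 100-year records for the slope-coverage experiment (so the
  ±2 SE criterion sits near its asymptotic 95%), and 100 seeded
  replications of the two-region experiment.

## Limitations

* Per-cell significance ignores serial correlation and multiplicity; the
  stipple maps are descriptive, not a family-wise inference.
* The RATIO has no built-in uncertainty interval (a bootstrap over years
  is a natural extension).
* Conservative regridding of *extensive* quantities, map projections, and
  polygon/shapefile masks are out of scope; masks are rectangular in
  coordinates or user-supplied weight tables.
* The alternative see-saw metric based on mean-to-mean-absolute anomaly
  ratios is noted in the literature but not implemented here.

## A short worked run

```{r}
res <- run_pipeline(list(preset = "two-region", seed = 1, years = 6,
                         detrend = FALSE))
res$summaries
res$contrasts
glance(res$regional$west$modes$gpp)[1:2, ]
```
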