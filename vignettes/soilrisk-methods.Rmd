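---
title: "Methods: soil metal(loid) screening, indices and health risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil metal(loid) screening, indices and health risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilrisk)
```

This vignette documents the models implemented in **soilrisk**, the
choices behind their defaults, and what the synthetic survey generator
does and does not emulate.

## Guideline screening

A sample is screened against a *guideline set*: a named map from metal
symbol to a threshold concentration in mg/kg dry soil, of kind
`permissible` (national standard), `target` or `intervention` (the Dutch
Soil Guideline pair, where the target value marks sustainable soil
quality and the intervention value serious contamination). Three
built-ins ship with the package: the Mongolian soil-quality standard
MNS 5850:2019 and the Dutch target and intervention values. The
registry is data-driven — `read_guideline_config()` merges a plain-text
`metal = value` file over any built-in — because national standards are
periodically revised and users need to swap in local values without
touching code.

Two conventions matter and are fixed deliberately:

* **Exceedance is strict** (`concentration > threshold`). A permissible
  value denotes the largest admissible content, so a sample exactly at
  the threshold is compliant. In continuous concentration data exact
  ties are measure-zero anyway.
* **Missing concentrations are flagged, never dropped silently.** A
  metal without a value (or without a threshold in the chosen set)
  appears in the screening output with `evaluable = FALSE` and is
  excluded from exceedance counts. This mirrors real survey practice,
  where the less routine metal(loid)s (As, Cr, Hg, Ni) are often
  measured only in a sample subset.

Values below the detection limit are accepted as reported; no automatic
DL/2 substitution is applied, since substitution policy is a survey-level
decision that should be made explicitly by the analyst before screening.

## Pollution indices

Per metal, the pollution index is the dimensionless ratio
$PI_i = C_i / T_i$ against the permissible content. A sample is
summarised by the integrated Nemerow index

$$IPI_N = \sqrt{\frac{PI_{avg}^2 + PI_{max}^2}{2}},$$

whose defining property is the extra weight on the single worst
pollutant: algebraically $PI_{max}/\sqrt{2} \le IPI_N \le PI_{max}$ and
$IPI_N \ge PI_{avg}$, which the test suite asserts on randomly generated
index vectors. The five-class scale is safe ($\le 0.7$), precaution,
slight, moderate and heavy ($\ge 3$) pollution. The published scale
fixes the outer closures ("$\le 0.7$", "$\ge 3$"); the interior
boundaries are assigned left-closed — precaution $(0.7, 1)$, slight
$[1, 2)$, moderate $[2, 3)$ — so that the partition is total and
disjoint. The default metal set is Cd, Cu, Pb, Zn (the metals measured
in every sample of the survey design the package emulates); any subset
with thresholds can be selected.

Because the index is nonlinear, the mean of per-sample $IPI_N$ values
and the $IPI_N$ of the town-mean concentrations differ in general.
`survey_ipin()` reports both, labelled `mean_ipin` and `ipin_of_means`,
rather than privileging either aggregate.

## Human health risk assessment

The deterministic exposure model covers the two dominant soil pathways,
ingestion and dermal contact (inhalation contributes little for
metal(loid)s in soil and is deliberately not implemented):

$$ADD_{ing} = \frac{C_{soil} \cdot IngR \cdot EF \cdot ED}{BW \cdot AT}
  \times 10^{-6}, \qquad
  ADD_{derm} = \frac{C_{soil} \cdot SA \cdot AF \cdot ABS \cdot EF \cdot
  ED}{BW \cdot AT} \times 10^{-6}.$$

Built-in receptor scenarios (overridable via `exposure_scenario()`):

| parameter | unit | adult | child |
|---|---|---|---|
| IngR, soil ingestion rate | mg/day | 100 | 200 |
| EF, exposure frequency | days/year | 350 | 350 |
| ED, exposure duration | years | 24 | 6 |
| BW, body weight | kg | 65.0 | 15.9 |
| SA, exposed skin area | cm² | 4350 | 1600 |
| AF, adherence factor | mg/cm² | 0.07 | 0.20 |
| LT, lifetime | years | 70 | 70 |

The averaging-time convention is $AT_{nc} = ED \times 365$ days (8760
adult, 2190 child) for non-carcinogenic quotients and
$AT_{ca} = LT \times 365 = 25550$ days for carcinogenic risk, for both
receptors. The body weights reflect Mongolian adults and values used in
neighbouring China for children — the populations of the survey design
the defaults target.

Hazard quotients are $HQ = ADD / RfD$ per pathway with pathway-specific
reference doses, and $HI = HQ_{ing} + HQ_{derm}$; $HI > 1$ flags
potential non-carcinogenic effects. Carcinogenic risk is
$CR = ADD_{ing}(AT_{ca}) \times SF_{ing}$ for the metals with an oral
slope factor (Cd and Pb in the built-in profile). **CR uses the
ingestion pathway only**: the toxicity profile provides no dermal slope
factors, and extrapolating oral slope factors to the dermal route would
add unsupported precision. Asking for CR of a metal without a slope
factor is an error rather than a silent zero, so "no carcinogen" can
never be confused with "no risk". Categories follow the regulatory
bands: virtually safe ($\le 10^{-6}$), acceptable ($10^{-6}$–$10^{-4}$),
unacceptable ($\ge 10^{-4}$).

All dose and risk quantities are linear in concentration, so the average
risk of a set of samples equals the risk of the average concentration —
`risk_table()` exploits this, and the equality (exact, not approximate)
is property-tested. Risk outputs print in scientific notation with three
significant figures, the conventional precision of such tables.

## The synthetic survey generator

No public dataset accompanies the survey design the package emulates, so
the generator is first-class, tested code rather than a test fixture. It
reproduces the design's statistical skeleton:

* **Hexagonal sampling networks.** `hex_grid_points()` lays a triangular
  lattice over the town rectangle, choosing the pitch by bisection so
  the clipped point count is exact; surplus points nearest the boundary
  are dropped deterministically. Three towns with 48, 50 and 44 samples
  give the canonical 142.
* **Lognormal concentrations.** Trace-metal concentrations in soil are
  classically right-skewed; each metal is drawn i.i.d. lognormal with
  parameters solved from the target arithmetic mean $m$ and coefficient
  of variation $cv$: $\sigma^2 = \log(1 + cv^2)$,
  $\mu = \log m - \sigma^2/2$, so the expectation is exactly $m$. The
  default $cv = 0.5$ is a typical mid-range dispersion for urban topsoil
  surveys; $cv = 0$ degenerates to the constant-at-mean limit, and
  negative values are rejected.
* **Hotspots.** Enrichment is multiplicative with linear decay inside a
  radius — a town-centre cluster for each town and an additional eastern
  mining-waste gradient for the third town, mimicking the narrative
  pattern of coal-town pollution (older town cores and waste heaps).
* **Mean-exact mode with controlled exceedances.** `fixture_towns()`
  post-scales each town/metal series so the arithmetic mean equals the
  reference town mean to machine precision, injects exactly one Cu
  exceedance and three Pb exceedances of the Mongolian permissible
  values at hotspot-adjacent samples, and compensatorily rescales the
  remaining samples. The rescaling caps every non-injected sample at
  0.98 of its threshold (iterating the cap-and-rescale step until the
  target sum is met exactly), which guarantees the exceedance counts
  for any seed while preserving the exact means.

What the generator does **not** emulate: measurement error and
censoring at detection limits, spatially autocorrelated background
fields beyond the hotspot structure, correlation between metals, and the
true per-sample distributions of any real survey (only means and a
dispersion level are matched). Passing tests therefore demonstrate that
the assessment chain is correct on data with the right design and
first-moment structure, not that any particular real survey would yield
the same per-sample results.

## Spatial interpolation

Maps are produced by the compute-then-interpolate route: the per-sample
$IPI_N$ is computed first and then interpolated
(interpolate-then-compute is available by interpolating concentrations
and computing indices on the raster, but the index of interpolated
concentrations is not the interpolation of indices, so the default
follows the variable actually mapped in practice). Two interpolators are
provided:

* **IDW** with power 2 — predictions are convex combinations of
  neighbour values, hence bounded by their range.
* **Ordinary kriging** with a classical semivariogram (spherical,
  exponential or Gaussian). The empirical semivariogram is computed on
  at least 8 distance bins up to two-thirds of the maximum pair
  distance, and the model is fitted by weighted least squares with pair
  counts as weights. The WLS surface has local minima in which the range
  collapses toward zero (a pure-nugget look-alike), so the fit is
  multi-started from four range initialisations and the best objective
  kept. Empirical Bayesian variants with proprietary semivariogram
  families are intentionally out of scope; ordinary kriging preserves
  the scientific contract — an exact interpolator with an uncertainty
  surface and weights that sum to one.

Prediction uses a circular search neighbourhood (default radius 500 m,
up to 16 nearest neighbours); raster cells with no sample inside the
radius are nodata, the default cell size is 10 m, and output is written
as a plain-text ESRI ASCII grid. Numerical details: a prediction point
coinciding with a sample (distance < 1 nm) returns the sample value
directly, making interpolation exact regardless of solver conditioning;
a singular kriging system falls back to a ridge-regularised solve; a
constant field degenerates kriging to a constant surface with a warning.
Duplicate sample locations are averaged with a message before fitting.
Leave-one-out cross-validation (`cross_validate()`) reports mean error
and RMSE.

## Between-town comparisons

Concentration series are compared between towns with the two-stage
procedure standard in this literature: a Shapiro–Wilk normality check
per town at $P > 0.01$, then one-way ANOVA if every town passes and the
Kruskal–Wallis test otherwise. The gate is applied per metal per town,
never pooled; $\alpha = 0.01$ is fixed by convention. No post-hoc tests
or multiplicity corrections are applied — the output is one test per
metal, as such surveys report. A constant series is routed to the
nonparametric branch (normality is taken as failed), since the
Shapiro–Wilk statistic is undefined at zero variance. Under the null the
gated procedure keeps its nominal type-I error, which the suite verifies
by simulation.

## Problem sizes and determinism

The property-style tests use sizes chosen to make sampling variability
negligible relative to the asserted bands: 1,000 random vectors for the
index bounds and risk linearity, $n = 10{,}000$ draws for lognormal
parameter recovery (3-standard-error bands), 2,000 simulations for the
type-I calibration ($5\% \pm 1\%$), five simulated Gaussian fields of
180 points for variogram recovery, and a 4,800-sample survey for
generator moment checks. All simulations are integer-seeded with no
time-based entropy; the fixture survey is byte-identical across runs and
platforms for a given seed.

## Known limitations

* Risk is deterministic: no Monte-Carlo propagation of exposure-factor
  uncertainty, no bioaccessibility adjustment, no dermal slope factors.
* Background-value-based indices (geoaccumulation index, enrichment
  factor) are out of scope; all indices are guideline-normalised.
* The spatial module is planar and CRS-agnostic; it does not reproject
  coordinates or render basemaps.
* The generator matches means and a dispersion level, not full
  distributions; medians and quartiles of real surveys are not
  reproduced.
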