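---
title: "Ensemble SDMs for wetland plants: models, protocol, and validation on synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs for wetland plants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Species distribution models (SDMs) relate species occurrence to
environmental conditions and are a core tool for conservation planning.
Wetland plants — and mosses in particular — pose specific difficulties: their
distributions depend on hydrological conditions (groundwater, inundation,
topographic moisture accumulation) that standard climate-and-soil SDMs miss,
and the modelling workflow involves many small protocol decisions (plot
filtering, spatial thinning, absence sampling, ensemble weighting,
thresholding) whose combined effect is hard to audit on real data, where
truth is unknown.

`wetsdm` implements the complete workflow — bespoke hydro-climatic covariate
derivation, a plot-preparation protocol, a TSS-weighted GLM/GAM/BRT ensemble,
and spatial plus ecological niche validation — and exercises it entirely on
**synthetic landscapes and species with known truth**. Every species has a
known Gaussian niche; every protocol rule has a generator that plants
violations in known proportions. The tests therefore score the workflow
against ground truth rather than against itself.

## The synthetic world

`gen_landscape()` produces every raw layer the workflow consumes on an
aligned 1-km grid (cell centres at `(col + 0.5, row + 0.5) * cell_size`,
row 0 at the top):

* **Abstract covariates** are zero-mean, unit-variance Gaussian random
  fields, built by circular FFT convolution of white noise with a Gaussian
  kernel. Only two properties of real covariate stacks matter downstream —
  spatial autocorrelation and collinearity — so a full geostatistical
  simulator would add nothing. Collinearity is *constructed*: a
  `collinear_spec` entry rebuilds one covariate as a weighted sum of others
  plus noise, giving variance-inflation screening a known answer.
* **Monthly climate** is a smooth annual-mean temperature field plus a
  spatially varying seasonal amplitude (so the coldest-month temperature and
  growing degree days are correlated but not collinear), and a positive
  precipitation field with a mild seasonal cycle.
* **Topography and flow**: a smooth DEM whose pits are filled by monotone
  carving (iterated morphological reconstruction with an epsilon increment),
  then single-direction (D8) steepest-descent routing. The epsilon fill
  guarantees every interior cell has a strictly lower neighbour, hence an
  acyclic flow grid — the property flow accumulation needs.
* **Wetness counts, land cover, coastline**: binomial water/wet observation
  counts driven by a latent wetness field; categorical EUNIS-style land-cover
  codes; a coastline polyline along the western edge.

Species truths are separable Gaussian niches,
`PoO(cell) = p_max * prod_k exp(-(x_k - mu_k)^2 / (2 sigma_k^2))`, over named
driver covariates. Plots fall uniformly over cells; presences are Bernoulli
draws from the truth at the plot's cell; independent "GBIF-like" occurrence
records are importance-sampled in proportion to the truth. Noisy ordinal
indicator values (EIVs) are ranked, binned copies of the true optima, with an
optional sign flip per variable (mirroring indicators, such as moisture
against groundwater-table depth, that run in opposite directions).

What the generator deliberately does **not** emulate: real European
geography, dispersal limitation and biotic interactions, spatially biased
sampling effort, and non-Gaussian (skewed, bimodal) niches. Passing tests
therefore demonstrate that the workflow recovers what it assumes — unimodal
niches sampled without spatial bias — not that it is robust to violations of
those assumptions.

The paper-scale inputs (about 1.6 million plots, hundreds of species across
Europe) are not reproducible at desk scale. Default problem sizes are the
package's own choice of a realistic desk-scale regime: a 70 x 70 km grid,
12,000 plots, 12 species (4 per group), 2,000 candidate occurrence records
per species; the parameter-recovery suite uses a 90 x 90 grid, 20,000 plots
and 21 species. Attribute-noise fractions default to 5% per filterable
defect; ordinal EIV noise defaults to 0.5 scale steps.

## Derived environmental covariates

* **PET** per month is piecewise linear in monthly mean temperature: 0 below
  0 °C, `58.93 * T` between 0 and 30 °C, capped at `58.93 * 30` above. It is
  continuous at both breakpoints, non-negative and monotone.
* **Water balance** is the annual sum of monthly precipitation minus PET.
* **Growing degree days**: monthly means are interpolated to a 365-day
  series between month midpoints (non-leap calendar, December wrapping to
  January), and GDD accumulates the daily excess over a 5 °C base,
  `sum(max(T_day - 5, 0))` — the standard agro-climatological degree-day
  definition. The phrase "sum of daily temperature values above 5 °C" can
  also be read literally as summing the temperatures themselves on warm
  days; that reading is implemented behind `convention = "literal"`, but the
  degree-day reading is the default because it is the field's standard usage
  and the only one that makes the quantity continuous in temperature.
* **WWPI** `= (n_water + 0.75 n_wet) / n_total * 100`, nodata where no valid
  observations exist.
* **TWI** `= ln(a / tan beta)`, with contributing area per unit contour
  width from D8 accumulation (cell count x cell size) and the downstream
  slope floored at `1e-6` so flats and outlets never divide by zero.
* **Flow accumulation** follows the AreaD8 convention: a cell's accumulated
  value includes its own weight. Accumulation is evaluated in topological
  order and fails loudly on a cycle.
* **Upstream anthropogenic land cover** accumulates the cell areas (km²) of
  cells whose land-cover code is arable/market-garden (V1) or
  constructed/industrial (J).
* **Salt influence** flags cells within an inclusive 3 km Euclidean buffer
  of the coastline, in projected grid coordinates (a geodesic buffer would
  differ negligibly at this scale and is out of scope along with all real
  reprojection; inputs must arrive on one aligned grid and a validation
  error is raised otherwise).

## Plot protocol

Filtering retains plots surveyed 1990–2018, with location uncertainty at
most 1 km (inclusive), habitat code outside the excluded classes (marine MA,
inland water P, vegetated man-made V; level-1 prefix match), and no missing
covariate value at the plot's cell. Presences are thinned to one plot per
occupied 1-km cell (cells are half-open, membership by `floor(x / cell)`).
The minimum-presence rule requires the smallest `n` with
`floor(0.8 n) >= 5 * n_vars` presences — 94 for 15 variables — so that five
presences per variable survive the 20% hold-out. Absences are drawn from
one plot per cell where the species was not recorded, excluding presence
cells (so presence and absence cells are disjoint): at least 10,000 for
GLM/GAM and 1,000 for BRT, matched to the presence count when that is
larger, capped (with a warning) at the pool size. The 80/20
calibration/evaluation split is stratified by presence/absence label — the
source protocol says only "random sample", but an unstratified split can
leave an evaluation set with a single class at low prevalence, which makes
AUC/TSS undefined; stratification is the package's choice and changes
nothing else. Each protocol component consumes its own child seed derived
from one global seed by fixed offsets, so regenerating one component never
shifts another's random stream.

## The ensemble

Covariates are first screened by iterative VIF filtering: drop the variable
with the highest VIF above 10, recompute, repeat; ties break by variable
name. VIF is the diagonal of the inverse correlation matrix (equivalently
`1 / (1 - R²)` from regressing each variable on the rest), with perfectly
collinear variables reported as infinite.

The three techniques deliberately pin down behaviour that the original
modelling platform fixed only by package version:

* **GLM** — binomial-logit with linear plus quadratic terms per covariate,
  no stepwise selection (determinism).
* **GAM** — binomial-logit with a spline per covariate, basis dimension 4,
  REML smoothing selection (mgcv).
* **BRT** — gradient-boosted trees with logistic loss. The reference
  defaults (2,500 trees, learning rate 0.001, interaction depth 7, bag
  fraction 0.5) are the function defaults; the pipeline's default
  configuration uses 300 trees at learning rate 0.05 and depth 3, a
  desk-scale setting that trades a little smoothing for an order of
  magnitude in time. Boosting runs single-threaded with a fixed seed, so
  fits are bit-reproducible.

GLM and GAM covariates are z-scored from the calibration data; trees see raw
values. Covariates with too few unique values for a quadratic or a smooth
(e.g. the binary salt flag) enter as plain linear terms.

AUC is the Mann–Whitney rank statistic with ties counted one half. TSS is
maximised over the fixed grid 0, 0.001, …, 1; among tied maxima the smallest
threshold wins, and binarisation is inclusive (`PoO >= threshold`) so the
stored sensitivity/specificity are exactly reproduced. Ensemble weights are
the members' cross-validated TSS, clipped at zero (a worse-than-random
member should not vote) and normalised; all-zero weights fall back to equal.
Member skill and the ensemble are evaluated on the held-out presences plus
the large absence sample (the BRT's small absence set exists to speed up
tree fitting, not to define the evaluation population). Species are retained
when ensemble TSS ≥ 0.3 and AUC ≥ 0.7 (inclusive), then all members are
refitted on 100% of the data; weights remain the cross-validated ones.

Variable importance is permutation-based: shuffle one column, importance is
`1 - cor(original predictions, shuffled predictions)`, averaged over 3
permutations (variance reduction at trivial cost), floored at 0 and capped
at 1; an undefined correlation (constant predictions) counts as 1, i.e.
importance 0. Ensemble importance is the TSS-weighted mean across members,
computed on the full (presence + large absence) data — the source is silent
on calibration-only vs full data, and the refitted final models see all data
anyway.

## Validation

**Spatial**: ensemble probabilities are binarised at the maxTSS threshold
and compared against independent occurrence records — cleaned of flagged
geospatial issues, years outside 1990–2021, uncertainties above 1 km and
out-of-area locations, then thinned to one record per cell — via the true
positive rate (TPR), the fraction of records in predicted-present cells.
Species with no surviving records are excluded from TPR summaries.

**Ecological**: response curves use the evaluation-strip method — vary one
covariate over its range *in the presence plots* while holding the others at
their presence-plot means (the range is taken over presences, not the whole
map, for consistency with the means in the same construction), combining the
member curves by the same TSS weights. The modelled indicator value (MIV) is
the curve's argmax; ties within 1e-12 on the probability axis take the
median of the tied positions, so a flat curve yields the range midpoint.
MIVs are paired with EIVs for configured indicator-variable pairs, admitting
a species only when that variable's ensemble importance is at least 0.05,
and scored per species group by Spearman rank correlation (mid-ranks for
ties; two-sided p from the t approximation on n − 2 degrees of freedom,
reported as NA below 3 species). No multiple-testing correction is applied
across pairs, matching the source analysis.

## Numerical and degenerate-input choices

* Slope floor 1e-6 in TWI; epsilon 1e-4 in pit filling.
* MIV tie tolerance 1e-12; `extract_miv` is invariant under strictly
  monotone rescaling of the probability axis.
* Zero-range strip variables, empty absence pools, single-class evaluation
  sets, cyclic flow grids, degenerate ordinal scales and zero-variance rank
  vectors all raise explicit errors rather than returning silently.
* Nodata (`NA`) propagates through every raster operation and excludes
  plots at extraction time.

## Limitations

Results on synthetic landscapes bound what can be claimed about real
wetland data: the generator has no sampling bias, no dispersal structure,
and separable Gaussian niches, so recovery rates here are an upper bound on
field performance. MIVs at the edge of the sampled range are biased outward
(the strip cannot see beyond the presence data), which is visible for
species whose true optimum sits near the covariate's observed extreme.
Niche breadth, multiple optima and realized-vs-fundamental niche
distinctions are out of scope.
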