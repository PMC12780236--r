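---
title: "Multiscale resource selection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale resource selection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfscape)
```

rsfscape implements a range-wide, multiscale resource selection function
(RSF) workflow for GPS telemetry: it compares environmental conditions at
locations an animal used with conditions at locations that were available
to it, estimates the spatial scale at which each covariate acts, fits a
mixed-effect used/available model, projects relative habitat suitability
onto the landscape, validates the projection with presence-only metrics,
and overlays the result on conservation geographies. Because telemetry
data of large carnivores are often restricted, the package ships a
synthetic-data generator with known selection coefficients and known
scales of effect, so every stage can be tested against recoverable ground
truth.

## The used/available design

Fixes are first spatially rarefied to one per 500 m pixel per individual
(the chronologically first fix in a pixel is kept; collar duty cycles vary
by orders of magnitude and would otherwise weight individuals by fix
rate). The area available to an individual is the union of discs around
its retained fixes, with radius

\[ d = 7 \sqrt{A_{hr}}, \]

where \(A_{hr}\) is the mean home-range area (km²) for the individual's
sex and region — an isometric approximation to median mammalian dispersal
distance. Within this domain, 10 background points are drawn per used
point, uniformly over free pixels, with no two design rows of any kind
sharing a pixel within an individual. "Did not overlap" is interpreted at
pixel granularity: exact coordinates almost never coincide, and the 500 m
pixel is the analysis unit throughout. Each background point inherits the
calendar month of its matched used point so both sides of a pair see the
same covariate snapshot when layers are time-labelled. Drawing is
equivalent to rejection sampling with re-draws on collision; the
implementation samples distinct free cells directly, which has the same
law and cannot stall. Presences are finally split 80/20 into training and
validation sets, stratified by individual so that no animal appears only
in validation; background rows follow their matched presence.

## Scales of effect

Each covariate is smoothed with an isotropic Gaussian kernel at seven
candidate scales (0.5, 1, 2, 4, 8, 16, 32 km). The kernel bandwidth is
the scale itself (\(\sigma\) = scale, truncated at \(3\sigma\),
renormalized to sum 1), so the 0.5 km scale is approximately the native
pixel. Near grid edges and nodata the kernel is renormalized over valid
in-grid cells rather than mirrored or zero-padded, which avoids dragging
coastal cells toward zero; a cell becomes nodata when less than half of
the in-grid kernel mass falls on valid cells. Smoothing is exact FFT
convolution, tested to 1e-10 against a brute-force double loop, with a
batched path that transforms each layer and kernel once. Design values
are sampled at the containing pixel (no interpolation), and when a
covariate carries several time labels the layer nearest to the row's
month is used, ties resolving to the earlier label.

The scale of effect of each covariate is then chosen by fitting, on
training rows only, a univariate mixed model (intercept, covariate,
random intercept per individual) at each scale and retaining the scale
with the lowest AICc,

\[ \mathrm{AICc} = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}, \]

with \(n\) the number of design rows and ties resolved to the smaller
scale. Training-only optimization keeps the held-out validation honest.

## Model fitting

The RSF itself is a binomial logit GLMM of used (1) versus available (0)
on the scale-optimized covariates with a random intercept per individual,
which absorbs between-animal differences in overall use intensity; Wald
z statistics come with each coefficient. Reported fits use the Laplace
approximation (`lme4`, `nAGQ = 1`); the several-dozen univariate
screening fits of scale optimization use `lme4`'s faster `nAGQ = 0`
marginal approximation without derivative-based standard errors, since
only their likelihoods are compared. Used and available rows carry equal
weights, and the AICc sample size is the row count.

Candidate covariates at their chosen scales are reduced to the most
complementary subset (default 15) by greedy minimum-redundancy
maximum-relevance selection on Spearman correlations: the first pick
maximizes \(|\rho(x, \mathrm{case})|\), and each later step maximizes
relevance minus the mean absolute rank correlation with the already
selected set. The criterion is the difference form; ties break
alphabetically, making the selection deterministic and invariant to
candidate order. Relevance is taken against the response, the standard
formulation. The final multivariable model is fitted on training rows
with covariates standardized to training mean 0 / sd 1, and the
standardization constants are stored for prediction.

## Prediction, validation and overlay

A use/availability RSF estimates *relative* selection strength, not
occurrence probability, so the suitability surface is meaningful only up
to monotone transforms. The surface is the inverse logit of the
fixed-effect linear predictor (random intercept at 0) — a monotone choice
that keeps values in (0, 1) and leaves every rank-based downstream step
(equal-frequency bins, Boyce index, quartile masks) invariant. Valid
cells are cut into 10 equal-frequency bins; cells equal to a cut value go
to the lower bin, so counts are equal up to ties, and a constant surface
degenerates to one bin with a warning.

Validation instruments:

* **Boyce index** — the Spearman correlation (average ranks on ties)
  between bin rank and the ratio of predicted to expected frequency of
  held-out presences across the 10 bins. Expected frequencies are the
  valid-cell shares of each bin — cell counts, since the grid is
  equal-area. The fixed 10-bin variant is implemented, matching the
  binning of the prediction raster; the continuous moving-window variant
  is not built.
* **ROC/AUC** — via pROC, with the operational threshold at the ROC point
  closest to (0, 1), reported with its sensitivity and specificity.
* **Density regression** — ordinary least squares of independent density
  estimates on mean suitability within a 100 km² circular buffer
  (radius \(\sqrt{100/\pi} \approx 5.642\) km) around each estimate.
* **Raster correlation** — Pearson r over jointly valid cells against any
  co-registered external surface.

The conservation overlay classifies the top quartile of the surface as
highly suitable, either range-wide or separately within each ecoregion
(so a single dominant biome cannot absorb all highly suitable area).
Thresholds are the value of the cell ranked at 25% from the top; cells
equal to the threshold are flagged, so exactly 25% is flagged when values
are distinct and the rule is deterministic under ties. Zones are
raster-native cell sets under the half-open pixel rule (a cell belongs to
the zone containing its centre), which makes shares and partition sums
exact: summed-suitability shares over an ecoregion partition total 100%
to floating-point precision. Protected areas are merged into
same-country adjacent blocks before filtering (area strictly greater than
100 km², zone-level maximum elevation below 3000 m, intersection with the
100 km-buffered current range, with named exclusions subtracted). Zone
proportions fall into the five categories 100–75, 75–50, 50–25, 25–0 and
0%, boundaries assigned upward and exact zero kept separate. Elevation is
a unit-level attribute of each protected area, not a cellwise layer.

## The synthetic generator and what it does (not) show

Covariates are stationary Gaussian random fields: white noise convolved
with a Gaussian kernel on the torus (convolution method; sigma = half the
autocorrelation range) and standardized to mean 0 / sd 1. Individuals
receive sex- and region-specific home ranges, uniform activity centres
(edge-buffered by their availability radius when the grid allows), and
fixes drawn independently over the cells of their availability disc with
probability proportional to \(\exp(\sum_c \beta_c z_{c,s(c)})\), where
\(z_{c,s}\) is the covariate smoothed at its true scale and standardized.
Standardizing the truth layers makes each \(\beta_c\) a selection
strength per standard deviation at the generating scale; without it,
coarse-scale effects would be attenuated by the variance shrinkage of
smoothing and the ground truth would be scale-confounded by construction.
Timestamps advance one day per fix so month labels accumulate naturally.

Choices a user should know when interpreting recovery tests:

* The generator draws independent fixes — no movement autocorrelation,
  step lengths or turning angles. Passing recovery tests therefore shows
  the estimator is correct for the RSF sampling law, not that it is
  robust to serially correlated telemetry.
* A single landscape realization creates chance correlations between
  coarse-scale layers and the realized use surface (an omitted-variable
  leakage specific to simulated landscapes only a few coarse-scale patches
  wide; a real range-wide study spans thousands of them). The recovery harness therefore uses
  a 240 × 240 grid at 500 m (120 km side), a 1.5 km autocorrelation
  range, 4 km² home ranges (14 km availability radius, so the 30
  individuals sample quasi-independent patches), unit-magnitude
  coefficients and generating scales up to 8 km. These sizes are the
  harness's study conditions, chosen once on the identifiability grounds
  above.
* Zone geography is synthetic: ecoregions and countries are Voronoi
  partitions of seeded points, protected areas disjoint random rectangles
  with synthetic elevation attributes.

Degenerate inputs are handled explicitly rather than silently: constant
covariate columns are dropped from fits with a warning, constant rasters
flag the whole stratum (quartiles) or collapse to one bin (binning) with
warnings, empty availability domains and over-subscribed background
demands raise errors naming the deficit.

## Reproducibility

Every generator and sampler is a pure function of its arguments and an
integer seed. The pipeline orchestrator derives per-stage child seeds
from one master seed by stable string hashing, writes every intermediate
artifact (ASCII-grid rasters, CSV tables, JSON zone sets) and a manifest
with content hashes; re-running with the same configuration and seed
reproduces byte-identical artifacts. Defaults in `load_config()` are the
workflow's canonical constants: scales {0.5, 1, 2, 4, 8, 16, 32} km,
background ratio 10, training fraction 0.8, 10 bins, 15 covariates kept,
quartile 0.25, 100 km range buffer, 100 km² / 3000 m protected-area
filters.

## Known limitations

Step- and path-selection designs, sex-specific final models, spatial
autocorrelation corrections, model averaging, connectivity analysis and
ingestion of real covariate/zone databases are out of scope. The Boyce
implementation is the fixed 10-bin quantile variant. Vector-exact zonal
areas are approximated by cell counts (exact under the half-open pixel
rule, and the convention used for all reported areas at 0.25 km² per
cell).
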