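---
title: "Methods: hierarchical crop-type mapping from regularized image time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical crop-type mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`hiercrop` implements a hierarchical mapping pipeline for the three major
crops of a cool-temperate, single-cropping agricultural region (Northeast
China is the motivating system): a binary cropland mask is produced first,
and crop types (rice, maize, soybean, other) are then classified only within
the mask. The final map uses the code convention 0 = rice, 1 = maize,
2 = soybean, 3 = other (other crops and non-cropland merged).

The classifier input is not a single image but a regularized time series of
top-of-atmosphere reflectance. Per observation, ten *proxies* are computed:
three bands (RE2, SWIR1, SWIR2) and seven indices (NDVI, EVI, LSWI, NDSVI,
NDTI, RENDVI, REP). The physics the pipeline exploits is:

* **Rice** floods during transplanting (day-of-year 120–150). Water absorbs
  shortwave infrared, so SWIR1/SWIR2 drop far below the other crops while
  LSWI = (NIR − SWIR1)/(NIR + SWIR1) rises.
* **Maize vs. soybean** separate at peak season (day-of-year 200–240) in the
  red-edge domain: maize's denser, chlorophyll-richer canopy pushes
  RENDVI = (NIR − RE2)/(NIR + RE2) and the red-edge position
  REP = 705 + 35·((0.5·(ρ~RE3~ + ρ~red~) − ρ~RE1~)/(ρ~RE2~ − ρ~RE1~))
  above soybean's.

One printed variant of REP divides the *entire* `705 + 35(...)` term by
(ρ~RE2~ − ρ~RE1~); that form is dimensionally inconsistent with the red-edge
literature, so the standard form above is the default and the literal
variant sits behind `rep_literal = TRUE`.

## Temporal regularization

Irregular, cloud-screened observations over the growing season (day-of-year
90–300) are turned into a fixed 22-interval series in a fixed order:

1. **10-day median composites.** Interval starts 90, 100, …, 300; interval
   *i* covers [start, start + 10). Twenty-two starts (not 21) are used
   because the time-series feature block is 10 proxies × 22 intervals = 220
   features; the last interval covers [300, 310).
2. **Linear gap filling** between nearest non-gap neighbours. Leading and
   trailing gaps take the nearest observed value — filling never
   extrapolates, so reflectance cannot leave [0, 1] through interpolation.
3. **Savitzky–Golay smoothing** with a 70-day window (7 points) and a
   3rd-order polynomial. Edges are handled by evaluating the least-squares
   polynomial of the first/last full window at the edge offsets (the
   `mode = "interp"` convention), *not* by mirror padding: reflecting a
   polynomial is not a polynomial, so mirror padding would break the
   guarantee that any cubic passes the filter unchanged, which is one of
   this package's tested contracts. The centre weight of the (7, 3) filter
   is 7/21 = 1/3, a value checked against an independent least-squares
   oracle in the tests (weights (−2, 3, 6, 7, 6, 3, −2)/21).

Indices are computed per observation *first* and then composited — the
pipeline never composites raw bands and re-derives indices. Zero
denominators yield `NaN`, which compositing treats as invalid; a proxy with
no valid observation at all makes the pixel unclassifiable (dropped and
counted).

## Feature banks

Two candidate banks are materialized with structural sizes that are
constants of the method:

* **Cropland bank, 184 features** = 30 seasonal stage medians (10 proxies ×
  seeding 109–169 / growth 170–230 / harvest 231–291) + 100 annual
  statistics (min, max, mean, sd, amplitude, 5/25/50/75/95th percentiles ×
  10 proxies over the 22 values) + 54 textures (18 co-occurrence statistics
  × 3 stage-median NDVI images).
* **Crop bank, 255 features** = 220 time-series values (10 × 22) + 20
  greenest/wettest-composite proxies (the observation maximizing NDVI and
  the one maximizing LSWI; ties go to the earliest day) + 15 harmonic
  coefficients (c, a1, b1, a2, b2 of
  VI~t~ = c + a1·cos(3πt) + b1·sin(3πt) + a2·cos(6πt) + b2·sin(6πt),
  t = (DOY − 1)/365, ordinary least squares on the original valid
  observations of NDVI, EVI and LSWI; at least five observations required).

Texture choices the source method leaves open, fixed here: quantization to
32 equal-width levels over the *whole* stage image's range (so neighbouring
windows are comparable), symmetric normalized matrices for the four offsets
(0,1), (1,0), (1,1), (1,−1) with statistics averaged over offsets, a 9×9
window centred on the pixel (clipped at scene edges), and the 18-statistic
Haralick set (inertia duplicates contrast by definition). Degenerate
conventions: correlation of a zero-variance matrix is 1, information
measures with zero marginal entropy are 0, and the maximal correlation
coefficient of a single-level matrix is 1; the implementation exploits the
similarity A = D^−1/2^ P D^−1/2^ (so MCC is the second-largest |eigenvalue|
of a symmetric matrix) and is verified against a brute-force pair-counting
oracle in the tests.

## Feature selection

Two steps, mirroring the established multicollinearity recipe:

1. Rank all candidates by Mean Decrease Impurity from a 100-tree random
   forest and keep the top 50 (accuracy saturates near 50 in the source
   analysis, so `top_k = 50` is the default, not a tunable we revisit).
2. Compute the Spearman correlation matrix of the retained features, treat
   each feature's correlation profile (its row) as a vector, agglomerate
   with Ward linkage, cut the dendrogram at height 1 ("maximum depth 1"),
   and keep the highest-MDI feature of each flat cluster.

The cut is interpreted as a dendrogram-height cut (the depth-criterion
reading is the other possibility; linkage and height are exposed as
arguments). Because tree splits depend only on sample orderings and Spearman
correlation only on ranks, the selected set is *exactly* invariant under
strictly monotone transforms of any feature — a property the acceptance
tests assert rather than assume. Constant features, whose Spearman
correlation is undefined, become logged singleton clusters.

## Classifiers

The random forest is implemented in compiled code because no forest package
is available in the target environment: CART trees, Gini impurity, the four
platform defaults frozen as printed — 100 trees, minimum leaf population
10, variables per split = ⌊√p⌋ sampled per node, bag fraction 0.5 drawn
without replacement — and scikit-style MDI importances normalized to sum 1.
All randomness flows through R's RNG, so a seed fixes the model bit for bit.

The baselines operate on the same selected feature vectors: the spectral
angle mapper assigns the class minimizing arccos(⟨x, r⟩/(‖x‖‖r‖)) to the
class-mean reference spectrum (scale invariant), the spectral correlation
mapper maximizes the centred Pearson correlation (shift and scale
invariant). Hierarchical prediction gives stage-1 non-cropland pixels code
3 directly, so crop codes can never appear outside the cropland mask.

## Despeckling

Patches (8-connected components of equal code; 4-connectivity is an option)
strictly smaller than 0.1 ha — i.e. at most 9 pixels at 10 m — are
replaced pixel-wise by the majority code within a Euclidean disc of radius
100 m (10 pixels). The majority is computed on the *input* raster so the
result is independent of visit order; ties break to the smallest class
code; nodata never wins and is never assigned; exactly one pass is applied
(the operation is deliberately not iterated to a fixed point, and is not
idempotent in general).

## Accuracy assessment

Confusion matrices put map classes in rows and reference classes in
columns. OA = trace/total, UA = row-normalized diagonal (1 − commission),
PA = column-normalized diagonal (1 − omission), F1 = harmonic mean of UA
and PA; undefined ratios surface as `NaN` with a warning. Report rounding
is 2 decimals, half away from zero, matching the published tables. The
package ships the published 2017–2019 validation confusion matrices of the
Northeast-China 10-m crop maps as a plain-text fixture
(`inst/extdata/published_confusion_2017_2019.csv`, reconstructed from the
printed table under the constraint that every printed OA/UA/PA/F1
reproduces); the acceptance tests recompute OA 0.81/0.81/0.87, the 2017
rice UA 0.87 and three-year mean F1 0.93 (rice) / 0.83 (maize, soybean)
from those counts. Area comparison regresses mapped on reference area per
crop (ordinary least squares) and reports R².

## The synthetic world — what it is and is not

No imagery is distributed with the source maps, so a generator stands in
for the archive. Per class, each band follows a double-logistic seasonal
curve between a bare-soil baseline and a class-specific peak-canopy
spectrum; rice blends 70% towards a water end-member inside its flooding
window; "other" is a half grass-like (early, flat; stands in for
non-cropland) and half vegetable-like (short late cycle; the realistic
soybean confuser) mixture with the subtype recorded, which gives the
cropland stage its binary truth. Acquisitions are every 5 days (two-
satellite revisit) over day-of-year 90–300; clouds are i.i.d. Bernoulli per
observation (default probability 0.3), flagged invalid and blended towards
a bright cloud spectrum; reflectance noise is Gaussian (default sd 0.02,
a plausible TOA radiometric-plus-BRDF jitter; the source never quantifies
band magnitudes per crop, so magnitudes are free parameters fixed once to
look like the region's croplands). Scenes are rectangular field patches
(6–14 pixel sides by default) whose classes are allocated by largest-
remaining-quota so realized frequencies track the requested mix to within
about one patch.

What the generator does **not** model: between-field phenology spread,
mixed pixels, BRDF/topography, multi-year dynamics. A consequence worth
stating plainly: with deterministic class curves and i.i.d. noise the
classes are almost perfectly separable, so the end-to-end evaluation
reaches OA ≈ 1.0 and the RF-vs-SAM/SCM margins are small (though
consistently in RF's favour, and the optimal subset stays within 0.02 of
the full set — the directions the acceptance criteria assert). Green
end-to-end tests therefore establish that the pipeline is wired correctly
and preserves the published orderings, *not* that it would reproduce the
published real-data accuracies (OA 0.81–0.87, municipal R² ≥ 0.83), which
require the real archive and yearbooks and are excluded from numeric
acceptance except through the printed confusion matrices. Encouragingly,
the selection step picks 17–22 features from the 255 candidates on
synthetic data, inside the published 14–25 range, without any calibration
to that end.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (type 7).
* Medians of even counts: mean of the middle pair.
* All-gap proxy series, fewer than five valid observations for harmonics,
  singular harmonic designs: the pixel is dropped and counted, never
  silently filled.
* Greenest/wettest ties: earliest day-of-year.
* RF split search: first best split wins at equal impurity decrease
  (deterministic); candidate splits must leave at least `min_leaf` samples
  on each side.
* Rasters travel as ESRI ASCII grid (plain text, nodata 255) because no
  GeoTIFF-capable R package is available offline in the target environment;
  the format is read natively by GDAL, QGIS and ArcGIS. Configuration
  round-trips through JSON for the same reason (`variables_per_split = 0`
  encodes the √p default).

## Known limitations

* The cropland stage trains on one synthetic season; the source method
  merges three years of observations for its cropland mask. Counts and
  semantics match; multi-year compositing does not.
* The cloud screen is a documented surrogate (min of rescaled brightness,
  moisture and not-snow criteria, threshold 0.2): the exact adjusted
  cloud-score algorithm is not reproduced in the source.
* Agro-climate zones are opaque labels; no zone geometry exists, and
  cross-zone behaviour is untested beyond the routing contract.
* The despeckler is O(small-patch pixels × disc area) in plain R; fine for
  in-memory scenes, not for province-scale mosaics.
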