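# hiercrop

Hierarchical crop-type mapping from regularized satellite image time series.

`hiercrop` is for remote-sensing scientists who classify crops from
Sentinel-2-like reflectance time series. It reimplements, as a tested R
package, a complete mapping pipeline for rice/maize/soybean regions:
cropland masking followed by crop typing (map codes 0 rice, 1 maize,
2 soybean, 3 other), driven by the two physical signals that separate these
crops — the rice flooding signature (depressed SWIR1/SWIR2, elevated
LSWI = (ρ_NIR − ρ_SWIR1)/(ρ_NIR + ρ_SWIR1) during transplanting, day-of-year
120–150) and the maize/soybean red-edge contrast (RENDVI and the red-edge
position REP = 705 + 35·((0.5·(ρ_RE3 + ρ_red) − ρ_RE1)/(ρ_RE2 − ρ_RE1)) at
peak season, day-of-year 200–240).

The pipeline stages, each an exported module:

1. **Synthetic scenes** (`simulate_series`, `simulate_scene`) — a generator
   with class-specific double-logistic phenology, rice flooding, Bernoulli
   clouds and Gaussian noise stands in for the satellite archive.
2. **Spectral** (`spectral_index`, `cloud_score`) — seven indices plus
   RE2/SWIR1/SWIR2 passthroughs; surrogate cloud screen.
3. **Temporal** (`composite_10day`, `fill_gaps`, `sg_smooth`) — 10-day
   median composites on a 22-interval day-of-year 90–300 grid, linear gap
   filling, Savitzky–Golay smoothing (70-day/7-point window, cubic).
4. **Feature banks** (`build_cropland_bank`, `build_crop_bank`) — exactly
   184 cropland candidates (30 seasonal + 100 annual + 54 GLCM texture) and
   255 crop candidates (220 time-series + 20 greenest/wettest composite +
   15 harmonic-regression coefficients).
5. **Selection** (`select_features`) — Mean-Decrease-Impurity top-50, then
   Ward clustering of Spearman correlation profiles cut at height 1, one
   representative per cluster.
6. **Classification** (`rf_fit`, `train_zone`, `predict_hierarchical`,
   `sam_classify`, `scm_classify`) — a compiled CART random forest (100
   trees, min leaf 10, √p variables per split, bag fraction 0.5) with
   spectral angle / spectral correlation mapper baselines.
7. **Postprocessing** (`despeckle`) — patches under 0.1 ha replaced by the
   circular-window (radius 100 m) majority.
8. **Assessment** (`confusion_matrix`, `accuracy_metrics`, `area_compare`)
   — OA/UA/PA/F1 and mapped-vs-reference area R².

## Worked example

Simulate 150 labeled series per class, build the 255-feature crop bank,
select an optimal subset, and evaluate a forest on held-out samples:

```r
library(hiercrop)
par <- default_params()                      # rice/maize/soybean/other phenology
series <- unlist(lapply(seq_along(par), function(i)
  simulate_series(par[[i]], 150, seed = 10 + i)), recursive = FALSE)
bank <- build_crop_bank(series)              # 600 x 255 feature matrix
sel <- select_features(bank$features, bank$label, cfg = rf_config(seed = 1))
print(sel)
#> Feature selection: 21 of 255 candidates (top 50 by MDI, cut height 1)
#> selected: ts_swir2_140, ts_lswi_260, ts_swir2_130, ts_re2_140, ts_swir1_120, ...

set.seed(2); tr <- sample(nrow(bank$features), 300)
m <- rf_fit(bank$features[tr, sel$selected], bank$label[tr], rf_config(seed = 1))
cm <- confusion_matrix(predict(m, bank$features[-tr, sel$selected]),
                       bank$label[-tr])
cm
#>          reference
#> map       rice maize soybean other
#>   rice      77     0       0     0
#>   maize      0    81       0     0
#>   soybean    0     0      68     0
#>   other      0     0       0    74
round_half_up(accuracy_metrics(cm)$oa)
#> [1] 1
```

The selected names are the physics: flooding-window SWIR2/LSWI features
(`ts_swir2_140`, `ts_lswi_130`) pick out rice, peak-season red-edge and NDVI
features (`ts_rendvi_180`, `ts_ndvi_240`) split maize from soybean. The
perfect hold-out OA is a property of the synthetic world (deterministic
class curves + i.i.d. noise), not a claim about real imagery — see the
methods vignette (`vignettes/hiercrop-methods.Rmd`) for exactly what the
green tests do and do not establish.

The published validation confusion matrices of the 2017–2019 Northeast-China
10-m crop maps ship as a plain-text fixture; recomputing their metrics:

```r
m <- lapply(published_confusion_matrices(), accuracy_metrics)
sapply(m, function(x) round_half_up(x$oa))
#> 2017 2018 2019
#> 0.81 0.81 0.87
```

## Command line

```sh
Rscript -e 'hiercrop::crop_cli()' run-all --out runs/demo --seed 11 --size 40
```

runs simulate → features → select → train → classify → despeckle → assess on
a synthetic scene and writes `map.asc` (ESRI ASCII grid), `crop_selection.csv`,
`assessment.json` and a seed/config-hash manifest. Subcommands `simulate`,
`features`, `select`, `despeckle` and `assess` expose the stages separately.

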