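# nichemetrics

Evaluation metrics for presence-only ecological niche models (ENMs /
species distribution models), in geographic **and** environmental
space.

Presence-only model evaluation is hardest exactly where ENMs are most
used: true absences are unavailable, so full ROC AUC and other
confusion-matrix metrics rest on invented pseudo-absences, and in
dispersal-limited ("Wallace's Dream") configurations a model can score
well in geography while extrapolating far beyond any environment the
species has been observed in. `nichemetrics` evaluates a suitability
raster along three axes:

- **Geographic space** — binary maps from calibration-omission
  thresholds (minimum training presence at tolerance 0; the order
  statistic `v[floor(E*n)+1]` in general), omission rate on held-out
  occurrences, proportional suitable area, the one-tailed cumulative
  binomial test `P(X >= k), X ~ Bin(n, p)`, and bootstrap partial ROC:
  the partial AUC of the (area, sensitivity) curve over the band
  `sensitivity >= 1 - E`, divided by the 1:1 null over the same band —
  an AUC ratio in [0, 2] with 1 = random.
- **Information criteria** — `AIC = 2K - 2 ln L`, AICc, a
  normalization-invariant raster occurrence likelihood, and the
  parameter-counting rules `K = 2p` (quadratic no-interaction GLM) and
  `K = N (p + p(p+1)/2 + c)` (classification models).
- **Environmental space** — a principal-component space built on the
  study-area background (layers standardized, components retained to
  90% cumulative variance), the observed niche as a minimum-volume
  enclosing ellipsoid (Khachiyan's algorithm with Wolfe–Atwood away
  steps) over all occurrences, and on top of it: interpolation /
  extrapolation counts over unique environmental combinations (E-space
  index I), Jaccard similarity between modeled and observed niches plus
  the distance to the farthest extrapolated prediction (E-space index
  II).

A fully seeded virtual-species generator (`generate_scenario()`) builds
correlated environmental stacks, a Gaussian true niche, geographically
disjoint calibration populations with a held-out central population,
and pseudo-models of known quality (`matched`, `broad`, `overfit`,
`random`) — so the entire workflow runs end-to-end with no downloads.
Rasters are plain-text ESRI ASCII grids; occurrences are CSV.

## Worked example

```r
library(nichemetrics)

sc <- generate_scenario(42)
sc
#> enm_scenario (seed 42): 60 x 84 grid, 8 layers, 3 retained components
#>   occurrences: central = 7, north = 42, south = 61
#>   pseudo-models: matched, broad, overfit, random

calib <- sc$occurrences[sc$occurrences$population != "central", ]
test  <- sc$occurrences[sc$occurrences$population == "central", ]

report <- run_full_evaluation(list(
  models = sc$pseudo_models, space = sc$space,
  calib = calib, test = test,
  proc = list(E = 0.05, n_replicates = 100, resample_fraction = 0.5),
  mc_samples = 20000, seed = 42
))
report
#> enm_evaluation: 4 models, seed 42, 3-dimensional E-space
#>   matched  OR 0.00, area 0.79, interp 3460, extrap 541, J 0.544
#>   broad    OR 0.00, area 0.79, interp 3460, extrap 541, J 0.543
#>   overfit  OR 1.00, area 0.30, interp 1441, extrap 96, J 0.692
#>   random   OR 0.00, area 0.99, interp 3556, extrap 1414, J 0.417
```

Reading the rows: `matched` (the true suitability) anticipates all 7
held-out occurrences (omission rate 0.00) while marking 79% of the
area suitable; `overfit` misses every held-out occurrence and sits in
the low-interpolation/low-extrapolation corner; `random` predicts
nearly everything suitable. `matched` and `broad` are identical here by
construction — omission-based thresholds are rank statistics, so a
monotone recalibration cannot change the binary map (cut calibrated
models at a probability contour with `binarize(model, 0.5)` to separate
them; see the vignette).

```r
partial_roc(sc$pseudo_models$matched, test, E = 0.05,
            n_replicates = 100, seed = 42)
#> partial ROC: mean AUC ratio 1.390 (E = 0.05, 100 replicates of 0.5 x 7
#>   test cells), p(ratio <= 1) = 0.000

aic_result(6, -1187.17, n = 110)
#> AIC = 2386.34 (K = 6, lnL = -1187.17), AICc = 2387.16 (n = 110)

fit_mve(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#> ellipsoid: d = 2, center (0.5, 0.5), volume 1.5708
```

The last call fits the minimum enclosing ellipse of the unit square's
corners: its circumcircle, area pi/2.

A thin command-line wrapper ships in `inst/cli/nichemetrics.R` with
subcommands `synth`, `eval-g`, `eval-e` and `aic`; see the header of
that script for usage.

## Package layout

- `R/grid.R`, `R/io.R`, `R/occurrences.R` — grid geometry, ESRI ASCII
  raster and occurrence CSV input/output, cell assignment, grid
  thinning
- `R/espace.R`, `R/ellipsoid.R` — background PCA, projections,
  minimum-volume enclosing ellipsoids
- `R/gmetrics.R`, `R/icmetrics.R`, `R/emetrics.R` — the three metric
  families
- `R/synthdata.R` — the virtual-species scenario generator
- `R/report.R` — the end-to-end evaluation bundle and JSON/CSV reports
- `vignettes/evaluating-niche-models.Rmd` — models, assumptions,
  numerical choices, limitations
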