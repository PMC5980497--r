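---
title: "Evaluating presence-only niche models in geographic and environmental space"
author: "nichemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating presence-only niche models in geographic and environmental space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemetrics)
```

## The problem

Correlative ecological niche models (ENMs) link species presence records
to environmental layers and output a suitability surface over a
geographic grid. Evaluating such models is hard precisely where they are
most used: with presence-only data there are no true absences, so
confusion-matrix metrics (full ROC AUC, TSS, kappa) rest on pseudo-absences
that the modeler invented. The situation is worst in *Wallace's Dream*
configurations, where a species' range limits are set by dispersal
barriers rather than unsuitable climate: the observed occurrences then
under-sample the fundamental niche, the calibration data lack
environmental contrast, and a model can look excellent in geography
while extrapolating absurdly in environmental space.

This package implements an evaluation toolkit for exactly that setting.
It evaluates a model along three complementary axes:

1. **Geographic-space prediction of held-out occurrences** — omission
   rate against binary maps thresholded on calibration omission error,
   the proportion of area predicted suitable, a one-tailed cumulative
   binomial test combining the two, and bootstrap partial ROC.
2. **Fit to the calibration data** — AIC/AICc from a raster-based
   occurrence likelihood, with explicit parameter-counting rules.
3. **Behavior in environmental space** — how much of the prediction
   *interpolates* (falls inside the environmental envelope of the
   observed occurrences) versus *extrapolates* (falls outside it), how
   far the extrapolation reaches, and how similar the modeled niche is
   to the observed one.

The observed niche envelope is a minimum-volume enclosing ellipsoid
(MVE) fit to all available occurrences projected into a
principal-component environmental space.

## The statistics

### Thresholding and the binomial test

A continuous prediction is converted to binary with an omission-error
rule on the calibration occurrences: with predictions at calibration
cells sorted $v_1 \le \dots \le v_n$, the threshold for tolerance $E$
is the order statistic $v_{\lfloor En\rfloor + 1}$, and a cell is
suitable iff its value is $\ge$ the threshold. $E = 0$ is the *minimum
training presence* (0% calibration omission); $E = 0.05$ discards the
5% of calibration occurrences with the lowest predictions. Because the
comparison is closed at the threshold, the realized calibration
omission never exceeds $E$.

Given a binary map, the omission rate is the fraction of held-out
occurrences on unsuitable cells, and the proportional area is the
fraction of usable cells predicted suitable (plain cell counting; a
latitude-cosine weighting is available but off by default, since on a
few-degree extent the cosine varies by under 4%). The cumulative
binomial probability is the one-tailed tail
$P(X \ge k),\; X \sim \mathrm{Bin}(n, p)$ with $k$ the correctly
predicted test occurrences, $n$ the usable test occurrences, and $p$
the proportional suitable area: the probability of doing at least this
well by throwing darts. It is computed with the regularized
incomplete-beta tail (`pbinom`), which matches brute-force summation of
the probability mass function to $10^{-12}$ up to $n = 1000$.

### Partial ROC

Full ROC AUC weighs commission errors that presence-only data cannot
measure. The partial ROC restricts attention to the low-omission region:
per bootstrap replicate, half of the unique test-occurrence cells are
resampled with replacement; thresholds sweep the prediction's value
classes (all distinct values up to 1000, equal-quantile classes beyond);
each threshold yields a point (proportion of area suitable, sensitivity);
and the partial AUC of the curve segment with sensitivity $\ge 1 - E$ is
divided by the partial AUC of the 1:1 diagonal over the same segment.
The ratio is bounded in $[0, 2]$; 1 is random performance. The reported
p-value is the fraction of replicate ratios $\le 1$ ($\le$, the
conservative side). Because both curve coordinates depend only on value
ranks, any strictly increasing transform of the prediction leaves every
replicate ratio unchanged — the test suite checks this invariance
directly.

Under a null of i.i.d. uniform suitabilities and uniformly placed test
points, the mean replicate ratio sits near 1 with a small positive
offset (typically 1.01–1.05 with 25-point resamples): the bootstrap
sensitivity curve is a coarse step function that lies slightly above
the diagonal at the band edge. This is a property of the statistic at
small evaluation sample sizes, not of the implementation; it vanishes
as the number of test occurrences grows.

### AIC and parameter counting

$\mathrm{AIC} = 2K - 2\ln L$, with
$\mathrm{AICc} = \mathrm{AIC} + 2K(K+1)/(n-K-1)$ for occurrence count
$n$. The log-likelihood of a continuous raster is computed by
normalizing it to a probability distribution over usable cells and
summing the log normalized value at each occurrence record — so any
positive rescaling of the output (raw vs. logistic vs. cumulative
formats) gives identical likelihoods, and records sharing a cell each
contribute a term. Two parameter-counting helpers cover common cases:
a quadratic GLM without interactions on $p$ predictors has $K = 2p$
(intercept excluded), and a classification model (regression-tree
ensemble or genetic algorithm) has $K = N(p + \tfrac{1}{2}p(p+1) + c)$
with $N$ the mean number of nodes per tree (or individuals per
population), $p$ the predictor dimensionality and $c$ the per-split
penalty (3 when each split partitions records into true/false/unknown).
$N$ may be a non-integer average; the product is rounded. For models
whose internals this package does not run, $K$ is an input.

### Environmental-space indices

The environmental space is built by standardizing every layer to zero
mean and unit variance over the background (all non-nodata study-area
cells — not the occurrences) and retaining the smallest leading set of
principal components reaching 90% cumulative explained variance (at
least one). Standardizing first — i.e. a correlation-matrix PCA — is
the right call for climatic layers with incommensurate units. Loadings
are sign-normalized (largest-magnitude entry positive) so scores are
reproducible across linear-algebra backends.

The observed niche is the MVE of all available occurrences in this
space. The package fits it with Khachiyan's barycentric coordinate
descent plus Wolfe–Atwood away steps (convergence tolerance $10^{-7}$,
iteration cap 10,000, and a final rescaling that guarantees every input
point has membership $\le 1 + 10^{-9}$). The full-coverage fit is the
true minimum *enclosing* ellipsoid; a robust mode (`coverage = h/n`)
greedily peels the point with the largest classical Mahalanobis
distance before fitting, approximating an h-subset estimator. The
default is full coverage because the observed envelope should enclose
every occurrence.

All E-space analyses operate on *unique environmental combinations*:
suitable cells are projected into component space, rounded to 6
decimals (in component units) and deduplicated, so large homogeneous
regions do not dominate the counts.

- **Index I** partitions the unique suitable combinations into
  interpolation (inside the observed MVE) and extrapolation (outside).
  The two counts always sum to the number of unique suitable
  combinations.
- **Degree of extrapolation** is the Euclidean distance (raw component
  units) from the MVE centroid to the farthest suitable combination
  outside the MVE; it is zero exactly when the extrapolation count is
  zero.
- **Index II** pairs that distance with a Jaccard similarity between
  the modeled and observed niches. Two modes ship because the construct
  is genuinely ambiguous: `ellipsoid_volume` (default) fits an MVE to
  the model's suitable combinations and estimates
  $J = V_\cap / (V_1 + V_2 - V_\cap)$ by uniform Monte-Carlo sampling
  inside the smaller ellipsoid (seeded, $10^5$ samples by default);
  `discrete_cells` counts unique background combinations,
  $J = |S \cap M| / |S \cup M|$, which is exact and used wherever a
  test needs an exact value. When the suitable set densely fills its
  own MVE the two modes agree closely.

A model evaluated against these indices should be read as a point in
the (interpolation, extrapolation) plane: overly permissive models sit
high on both axes, overfit models low on both; for a
dispersal-limited species one typically wants high interpolation with
low extrapolation.

## The synthetic scenario generator

Because the interesting evaluation regime needs inputs no small test
fixture can provide — aligned multi-layer environments, disjoint
calibration populations, a held-out population, and models of known
quality — the package ships a fully seeded generator
(`generate_scenario()`). Its defaults define the study conditions used
throughout the test suite:

- **Grid**: 60 × 84 cells of 2.5 arc-minutes (a 2.5° × 3.5°
  coastal-temperate extent), the resolution of standard bioclimatic
  layers.
- **Environment**: 8 layers, each a low-frequency random cosine surface
  plus a random linear gradient, blended with a shared latent field
  with weight 0.82. That weight mimics the strong collinearity of
  bioclimatic variables and makes the 90%-retention PCA keep 3
  components, the dimensionality in which the E-space indices are
  typically read. At weight 0 the layers are nearly independent (mean
  absolute pairwise correlation < 0.2); at weight 1 they are affinely
  identical and the PCA collapses to one component.
- **True niche**: a Gaussian (bell-shaped) suitability response,
  `exp(-m/2)` with `m` the squared standardized-environment distance to
  a niche center divided by `niche_breadth^2` (default 3.5 background
  standard deviations — broad enough that each latitudinal band holds
  well over the requested number of occurrence cells across seeds).
  Bell-shaped responses are the physiologically expected form; the
  0.5-suitability contour is exposed as a `true_niche` ellipsoid.
- **Populations**: 42 northern and 61 southern calibration occurrences
  and 7 held-out central ones, sampled suitability-weighted *without
  replacement* over cells whose true suitability exceeds 0.5, within
  three disjoint latitudinal bands (rows 1–30%, 35–65%, 70–100% of the
  grid). Sampling cells without replacement means the occurrence sets
  are already thinned to one record per cell, the structure the metrics
  assume. The niche center is the mean environment of one anchor cell
  per band, which keeps all three bands feasible.
- **Pseudo-models**: `matched` (the truth itself), `broad` (the
  monotone flattening `truth^0.1`), `overfit` (truth masked to a
  2-cell neighborhood of the calibration cells) and `random`
  (i.i.d. uniform). These span the corners the indices must separate.

One subtlety is worth spelling out. Minimum-training-presence
thresholds are *rank* statistics: any strictly increasing recalibration
of a model (such as `broad = truth^0.1`) produces exactly the same
binary map as the original under an omission-based threshold. The
omission-threshold workflow (`run_full_evaluation()`) therefore cannot — and
should not — distinguish `matched` from `broad`; that is a real
property of omission thresholding, not a bug. When the package compares
pseudo-models in environmental space it instead cuts these calibrated
suitabilities at the fixed 0.5 probability contour, where `broad`'s
flattening genuinely admits far more environmental combinations. With
that operating point the three non-random pseudo-models land in their
designed corners in every tested seed: `broad` dominates `overfit` on
both index-I axes, and `matched` shows high interpolation with less
extrapolation than `broad`.

What the generator does **not** emulate: sampling bias and spatial
autocorrelation of real occurrence records, dispersal kernels, biotic
interactions, coastline/nodata masks, and the particular spatial
texture of real climate rasters. Passing tests on these scenarios
demonstrate that the metrics measure what they claim on inputs with
known truth — not that any particular real-world model is good.

## Numerical choices and conventions

- Grids are regular lon/lat with square cells; cells are indexed
  1-based, row-major, row 1 northernmost (the reading order of ESRI
  ASCII grids, and the natural indexing in R). Points are assigned to
  cells by half-open intervals `[edge, edge + cell_size)` anchored at
  the lower-left corner.
- Occurrence thinning uses a grid anchored at (−180, −90) — the tiling
  convention of global bioclimatic layers — and keeps the first record
  in input order per cell (deterministic and order-stable).
- Occurrences falling outside the grid or on nodata cells are excluded
  from metrics with a warning, never silently and never as an
  exception: coastal records routinely fall off rasterized land.
- ASCII rasters are written with 17 significant digits, so a write/read
  round trip is bit-exact for doubles.
- Randomness (partial ROC bootstrap, Monte-Carlo Jaccard, the
  generator) always flows through an explicit seed argument and is
  local to the call (`withr::with_seed`), so identical configurations
  give byte-identical reports.
- The MVE membership tolerance is $10^{-9}$; degenerate (affinely
  dependent) point sets are rejected with a pointer toward dimension
  reduction rather than silently regularized.
- Test-suite problem sizes: scenario grids of 5,040 cells, partial-ROC
  nulls on 10,000-cell rasters with 500 replicates, Monte-Carlo Jaccard
  at $10^4$–$10^5$ samples, and 20-seed sweeps for the qualitative
  geometry checks.

## Limitations

- The Jaccard intersection volume is Monte-Carlo; its error scales as
  $n^{-1/2}$ and identical ellipsoids evaluate to 1 only within that
  error (the discrete mode is exact).
- The robust MVE mode is a greedy approximation to an h-subset
  estimator, not an exact one.
- Only ESRI ASCII grids are read and written; there is no reprojection,
  no resampling, and no vector support.
- The partial-ROC null has the small-sample offset discussed above;
  with very few test occurrences (the regime the method is designed
  for) ratios are coarse and should be read through their replicate
  distribution, not the mean alone.
- AIC helpers count parameters by the stated rules; they do not parse
  any modeling software's internal files.

## A worked example

```{r example}
sc <- generate_scenario(42)
sc

calib <- sc$occurrences[sc$occurrences$population != "central", ]
test <- sc$occurrences[sc$occurrences$population == "central", ]

report <- run_full_evaluation(list(
  models = sc$pseudo_models,
  space = sc$space,
  calib = calib,
  test = test,
  proc = list(E = 0.05, n_replicates = 100, resample_fraction = 0.5),
  mc_samples = 20000,
  seed = 42
))
report
```

The `matched` and `broad` rows illustrate the rank-invariance point
above; the E-space report of `binarize(model, 0.5)` versus
`threshold_by_omission()` illustrates the difference between a
probability operating point and an omission operating point.
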