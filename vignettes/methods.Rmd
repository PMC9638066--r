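---
title: "Methods: UAV multispectral phenotyping of wheat yield and nitrogen use efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UAV multispectral phenotyping of wheat yield and NUE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatvis)
```

## The problem

Plot trials that test nitrogen (N) fertilizer response in winter wheat are
traditionally phenotyped by destructive harvest: grain yield per plot, and
from it the nitrogen use efficiency (NUE) traits. Five-band multispectral
cameras on small UAVs offer a cheap, non-destructive alternative: canopy
reflectance in blue/green/red/red-edge/NIR (450/560/650/730/840 nm) carries
information about biomass, chlorophyll and ripening that correlates with
final yield well before harvest. `wheatvis` implements the full computation
from raw digital numbers (DN) to evaluated trait-prediction models for a
standard split-plot trial: 4 N rates (0/100/200/300 kg N/ha) x 3 varieties
x 3 replicates = 36 plots of 2 m x 8 m, imaged at six growth stages from
jointing (J) through booting (B), heading (H), late flowering (LF), and
initial to late grain-filling (IGF, LGF).

Because no public imagery exists for such a trial at plot scale, the
package ships a synthetic scene generator that reproduces the *statistical
structure* the analysis assumes, so that every stage of the pipeline is
testable at desk scale.

## Radiometric calibration (empirical line method)

Raw DN are converted to surface reflectance per band with a zero-intercept
empirical line fitted on reference panels of known reflectance:

$$R = \mathrm{DN} \cdot a_i, \qquad
  a_i = \frac{\sum_j R_j \, \mathrm{DN}_j}{\sum_j \mathrm{DN}_j^2},$$

where $j$ runs over the panels (four grey levels, 0.05/0.20/0.40/0.60, by
default). The model has no offset term: a zero-DN pixel maps to zero
reflectance. Panel DN are extracted as the arithmetic mean over a central
0.2 m x 0.2 m square to avoid boundary mixing. Calibrated values above a
ceiling (`clip_max = 1`) are clipped with a logged count rather than
propagated — noisy bright panels can slightly exceed 1, and silent
super-unity reflectance would corrupt every downstream index.

With continuous (unrounded) DN and no noise, the fit recovers the
generator's true slopes to floating-point accuracy. Integer quantization of
16-bit DN alone bounds slope recovery near $10^{-5}$ relative; the
generator therefore exposes `dn_round = FALSE` for exact-inversion
validation, while the default (`TRUE`) matches the camera's integer TIFF
output.

The `percent_error()` utility (mean absolute percent error,
$100 \cdot \mathrm{mean}(|m - r|/|r|)$) supports comparing camera-derived
band reflectance or indices against an independent reference such as a
field spectrometer.

## Soil background removal

At early stages and in unfertilized plots, bare soil dominates the field of
view and drags plot-mean indices down. The pipeline computes the visible
atmospherically resistant index,

$$\mathrm{VARI} = \frac{G - R}{G + R - B},$$

which is strongly positive for green canopy and near or below zero for
soil, and thresholds it. The default threshold is Otsu's method on the VARI
histogram: 256 equal bins over the observed range, split maximizing
between-class variance; when several splits are equally optimal (an empty
gap between modes), the midpoint of the optimal plateau is used, so cleanly
separated classes split through the middle of the gap. A fixed threshold
can be supplied instead; thresholds outside the observed range produce an
empty or full mask with a warning, never an error. Pixels whose VARI
denominator magnitude falls below $10^{-6}$ are excluded as undefined.
Masking is applied uniformly at every stage. Mask quality against a
reference is summarized by confusion-matrix metrics (accuracy, IoU,
precision, recall) with canopy as the positive class.

## Vegetation indices and plot extraction

Nine indices are computed per pixel from calibrated reflectance: VARI,
NGBDI $=(G-B)/(G+B)$, NDVI, NDRE, GNDVI, CI~rededge~ $=N/RE-1$, MTCI
$=(N-RE)/(RE-R)$, mNDblue $=(B-RE)/(N+B)$, and repRVI $=R/N$ — the
reciprocal of the classic ratio vegetation index. Putting the red band in
the numerator makes repRVI sensitive to the rising red reflectance of
ripening canopies that the NIR-dominated RVI smooths over, which is what
makes it useful late in grain filling.

Plot values are masked zonal means: the mean of per-pixel index values over
pixels whose centres fall inside the plot polygon shrunk inward by 0.25 m
(avoiding boundary mixing between plots), that pass the canopy mask, and
are defined. Two genuinely open choices are pinned here and enforced by
regression tests:

* **mean-of-index**, not index-of-mean-reflectance — the two differ because
  indices are non-linear in the bands;
* plots with *no* qualifying pixels at a stage are flagged and dropped with
  a warning (recorded in the table's `empty_zones` attribute), never
  silently returned as NaN.

## Traits

Yield is expressed in kg/ha (`yield_to_kg_ha()` converts a sampled grain
mass over a harvested area; the sampled area is an explicit argument
because row-spacing conventions vary). The two NUE traits are

$$\mathrm{NPFP} = \frac{GY_{N_i}}{N_i}, \qquad
  \mathrm{aNUE} = \frac{GY_{N_i} - GY_{N_0}}{N_i}, \qquad i > 0,$$

both in kg yield per kg N, undefined at the zero-N control (requesting them
for $N_i = 0$ is an error, not a zero). The control yield $GY_{N_0}$ is
resolved by a pairing rule: default is the N0 plot of the same variety and
replicate; a variety-mean alternative is available. aNUE may legitimately
be negative and is not floored. The identity
$\mathrm{aNUE} = \mathrm{NPFP} - GY_{N_0}/N_i$ holds exactly by
construction and is asserted on every generated trait table.

## Correlation screening and stage generality

Each (index, stage) cell is Pearson-correlated with each trait (two-sided
t-test, $n-2$ df; significance marked at 0.05 and 0.01). NUE screens use
only the 27 fertilized plots. No multiple-testing correction is applied
across the matrix; the screen is exploratory, not confirmatory.

To pick indices that are robust to acquisition date, a weighted
mean/maximum rank-sum score aggregates the screen: at each stage indices
are ranked by decreasing $|r|$ (ties averaged), and

$$\mathrm{score} = w \cdot \mathrm{mean}_s(\mathrm{rank}) +
  (1 - w) \cdot \max_s(\mathrm{rank}), \qquad w = 0.5,$$

lower being better: strong on average *and* never weak at any stage. This
scoring is a reconstruction of the rank-sum family of stage-robustness
measures; the exact published weighting it stands in for is not available,
so `w` is configurable, only the reconstruction's own properties are
asserted (dominance, tie behaviour, $w = 1$ reducing to mean rank,
invariance to monotone rescaling of any index), and with a lower-is-better
orientation. $|r|$ rather than signed $r$ drives the ranking because
ratio-type indices (repRVI, mNDblue) correlate negatively by construction.

## Regression models and evaluation

Four families predict a trait from VI features (`<index>_<stage>` columns):

* **LR** — single-feature least squares;
* **MLR** — multi-feature least squares (rank-deficient designs are an
  error naming the offending columns);
* **SMLR** — bidirectional stepwise AIC selection starting from the full
  model (`MASS::stepAIC`), deterministic given the data;
* **PLSR** — NIPALS partial least squares with a univariate response;
  `ncomp = "cv"` picks the component count minimizing mean RMSE over
  seeded 5-fold cross-validation with folds stratified by N level. With
  full components on a full-rank design, PLSR reproduces OLS predictions —
  the package's own oracle test.

Evaluation is by repeated stratified splitting: within each N level,
two-thirds of the plots (half-up rounding, so 6 of 9) are sampled to train,
the rest to test; 20 repeats by default, repeat $k$ seeded `base_seed + k`,
so different model families evaluated with the same base seed see identical
partitions. Features are z-scored on the training set only, with the train
statistics applied to the test set. Metrics are $R^2$ (squared sample
Pearson correlation of observed vs predicted — the convention the usual
model-training software reports, and the dimensionally consistent reading
of the correlation-ratio formula), RMSE, and MAE. A failing repeat is
recorded with its seed and error; remaining repeats are unaffected.

## The synthetic scene generator

The generator emulates the trial per plot and per pixel:

* **Latent vigor**: $v = 1 + 2\,N/(N + 150) + \delta_{\mathrm{variety}} +
  \varepsilon$, saturating in N rate, with small variety offsets
  ($\pm 0.15$; the N treatment dominates the variance structure, matching
  how such trials typically behave) and plot noise (sd 0.08).
* **Yield**: $1500 + 2200\,v + \varepsilon$ kg/ha (noise sd 250), floored
  at zero. Defaults give ~3.7 t/ha unfertilized to ~6.6 t/ha at 300 kg
  N/ha, NPFP falling from ~55 to ~22 kg/kg as N rises — realistic
  magnitudes and the characteristic decreasing NUE trend.
* **Canopy cover** per stage:
  $\mathrm{plogis}(b_{\mathrm{stage}} + 1.2\,(v - 1.6))$ with stage
  intercepts from $-0.8$ (jointing: soil-dominated) to $1.8$ (late
  flowering: closed canopy), plus per-pixel noise (sd 0.04). The true
  canopy mask marks pixels with realized cover above 0.5 — an unambiguous
  segmentation target.
* **Spectra**: per-pixel reflectance is the cover-weighted linear mixture
  of the plot's canopy spectrum and bare soil, plus Gaussian sub-pixel
  noise, clipped to $[0,1]$. Canopy red/blue decrease and red-edge/NIR
  increase with vigor; visible-band coefficients are set so green canopy
  has VARI $\approx 0.6$ against soil at $-0.13$ — the clearly bimodal
  histogram real canopy/soil scenes show, and the contrast the VARI
  threshold method presumes.
* **DN**: $R/a_i$ plus Gaussian DN noise (sd 20), rounded to integers in
  $[0, 65535]$ (16-bit). Panels render at their known reflectance exactly.

What the generator does **not** emulate: radiative-transfer canopy optics,
BRDF/shadow/vignetting, photogrammetric distortion, weeds or residue,
spatial fertility gradients, and any real spectral response functions.
Consequently, passing tests demonstrate the *computational* correctness
and statistical behaviour of the pipeline under its assumed structure —
they say nothing about the field accuracy of any specific camera, and the
generator's correlation magnitudes are design choices, not predictions.

## Numerical choices and problem sizes

Denominator guard $10^{-6}$ for VARI and all indices; nodata propagates.
ELM clip ceiling 1.0 with logged counts. Otsu ties resolved to the plateau
midpoint. Split rounding half-up per stratum. Pixel inclusion by
pixel-centre-in-polygon with half-open cells, so adjacent polygons
partition the grid. Stage labels and band order are fixed vocabularies.

The configured default ground sample distance is 0.015 m (the camera class
this models resamples to 1.5 cm). The package's tests and the acceptance
script run the generator at 0.05–0.1 m GSD — plots of roughly 40 x 160
down to 20 x 80 pixels — which leaves hundreds to thousands of canopy
pixels per plot, far more than zonal means need for stable estimates,
while keeping a full multi-stage scene render to a few seconds. All
protocol counts (36 plots, 1944 VI records, 24/12 and 18/9 splits) are
GSD-invariant.

## Known limitations

* Rasters are held in memory as dense arrays; scenes beyond a few hundred
  megapixels would need tiling that the package does not implement.
* Plot and panel polygons are axis-aligned rectangles (the inward edge
  buffer exploits this); arbitrarily rotated trials are not supported.
* PLSR supports a single response; multi-trait PLS2 is out of scope.
* The TIFF writer emits plain multi-page TIFF with a JSON sidecar for the
  world transform, not tagged GeoTIFF; GIS round-tripping requires the
  sidecar.
* The stage-generality score is one member of the rank-aggregation family;
  rankings near ties can differ under other weightings, which is why `w`
  is exposed.
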