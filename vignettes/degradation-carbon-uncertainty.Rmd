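---
title: "Mapping forest degradation from canopy texture and propagating its uncertainty into carbon estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest degradation from canopy texture and propagating its uncertainty into carbon estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Selective logging and understory fire degrade tropical forests without
converting them to another land cover: the canopy stays mostly closed, but
structure and aboveground carbon are reduced. Moderate-resolution wall-to-wall
maps miss much of this damage, while very-high-resolution (VHR) imagery shows
it clearly as *texture* — logging leaves linear roads, skid trails and log
storage decks; recent fire leaves a diffusely darkened, fine-grained canopy
surface. `degratex` implements a complete, testable pipeline around that
observation:

1. compute the enhanced vegetation index (EVI) from a 4-band VHR
   surface-reflectance image;
2. describe local canopy texture with moving-window gray-level co-occurrence
   matrix (GLCM) metrics;
3. aggregate the texture metrics to a coarser classification grid and attach
   reference labels;
4. fit a purity-weighted, class-balanced gradient-boosted multinomial model
   that returns, per grid cell, a *probability* of being intact, logged or
   burned;
5. assess the hard (most-probable) map with a confusion matrix and user's /
   producer's accuracies;
6. build empirical site-by-class aboveground carbon density (ACD)
   distributions from plot-level carbon rasters;
7. propagate ACD and classification uncertainty into site-level carbon
   estimates with Monte Carlo simulation.

A seeded synthetic-landscape generator stands in for the imagery, reference
polygons and lidar carbon data, so every stage of the pipeline runs and is
tested without any download.

## The model and its assumptions

### EVI

EVI = 2.5 (NIR − Red) / (NIR + 6 Red − 7.5 Blue + 1), with the standard
published coefficients (G = 2.5, C1 = 6, C2 = 7.5, L = 1). Inputs are assumed
to be surface reflectance on the 0–1 scale; an integer scale divisor is
accepted for sensor-native encodings. Pixels whose denominator is
non-positive are set to nodata rather than returning an unstable ratio, and
nodata in any band propagates.

### GLCM texture

The raster is quantized into equal-width gray-level bins between its unmasked
minimum and maximum (32 levels by default; the common default of GLCM
toolchains — the binning scheme is a documented choice, since equal-width and
quantile binning are both defensible). In a centered moving window (45 px =
140.625 m at 3.125 m pixels by default), pixel pairs at the four unit
displacements (0°, 45°, 90°, 135°) are tabulated symmetrically (each pair in
both orders) and normalized. Eight metrics are computed per displacement —
mean, variance, correlation, contrast, homogeneity, dissimilarity, angular
second moment, entropy (natural log, 0·ln 0 ≡ 0) — and the *metric values*
are averaged across displacements, making the texture description
direction-free. Averaging metric values rather than matrices is the
convention of the moving-window texture packages this module mirrors.

Numerical conventions, each fixed and tested: correlation is defined as 0
when the window variance is 0 (constant window); a border of one full window
width is trimmed to nodata so edge windows with insufficient context never
contribute artifacts; displacements that find no valid pair (heavy masking)
are dropped from the average, and a pixel with no valid displacement is
nodata. The compiled moving-window path is required by test to agree with a
naive per-window R evaluation to 1e-10.

### Features on the classification grid

Each of the 8 texture bands is aggregated over 562.5 m grid cells (180 px)
with nine statistics — mean, SD, skewness, RMS, minimum, first quartile,
median, third quartile, maximum — giving 72 features per cell. Quantiles
interpolate linearly between order statistics (R type 7); skewness is the
population-moment ratio m3/m2^(3/2), defined as 0 for constant cells. Cells
with fewer than 50% unmasked pixels are dropped (a stand-in rule: keeping
slivers would compute statistics on unrepresentative samples).

Each cell's reference label is the dominant class of its pixels, with
*purity* the dominant class's share; exact ties are resolved by the fixed
priority burned > logged > intact. Disturbed cells whose event is more than
five years older than the image are excluded from training (the optical
degradation signal fades within a few years); the boundary is inclusive —
exactly five years old is retained. Features are centered and scaled within
each site using all of the site's cells. This matches how the multi-site
feature table is assembled before partitioning, and implies a mild train/test
leakage through the standardization statistics; it is documented here rather
than silently avoided, because per-site scaling with train-only statistics
would change what the features mean across sites.

### The probabilistic classifier

A stochastic gradient-boosted tree ensemble with a multinomial softprob
objective (xgboost backend) maps the 72 features to a probability vector over
(intact, logged, burned), encoded 0/1/2 throughout. Class imbalance is
handled by observation weights: the base weight of class *c* is N/(3 n_c), so
per-class weight sums are equal before each weight is multiplied by the
cell's purity, down-weighting heterogeneous reference cells.

Hyperparameters (all defaults of `training_spec()`): learning rate 0.2, tree
depth ≤ 4, ≥ 5 observations per terminal node, minimum split-loss reduction
0.2, 80% row and 70% feature subsampling per boosting round, early stopping
when the validation multiclass error fails to improve for 5 rounds. The
validation set is a 20% stratified carve-out of the training half — the size
is a design choice (the carve-out had to be defined somewhere); stratification
reuses the purity-bin strata. Data are split 50/50 into training and test
halves by stratified random sampling within class × purity bins of width 0.2
([0,0.2), …, [0.8,1]); singleton strata go to training. To account for
partition variability and algorithm stochasticity, the model is refit on 100
random partitions (`fit_ensemble()`), reporting the distribution of held-out
overall accuracies and per-cell test-fold probabilities averaged over
partitions. With a fixed seed and single-threaded boosting, every fit is
exactly reproducible.

### Accuracy assessment

The most-probable class per cell is compared with the reference in a 3×3
confusion matrix (rows predicted, columns reference). Overall accuracy is
trace/total; user's accuracy per class is the diagonal over the row sum
(complement of commission error); producer's accuracy the diagonal over the
column sum (complement of omission error). The confidence interval on
overall accuracy is the binomial normal approximation p̂ ± z√(p̂(1−p̂)/n),
clipped to [0,1]; the 100-partition accuracy spread is reported alongside as
an empirical alternative, since either could be quoted for a map of this
kind. Area-adjusted estimators are out of scope.

### Carbon distributions and substitution

Plot-level ACD (50 m, 0.25 ha) is aggregated to 500 m (25 ha) blocks by the
median of the 10×10 plot values, with blocks under 50% valid plots dropped.
The 500 m values are pooled by site × class, with no distinction by time
since disturbance, into empirical distributions (summaries use sample SD,
n−1). A class that a site's classifier can predict but for which the site
has no local carbon data (e.g. no burned forest was overflown there) is
*flagged*, then filled by pooling the same class from donor sites; every
substitution is recorded for the run manifest. The classification grid
(562.5 m) and carbon grid (500 m) deliberately differ and are only joined at
the site × class level — resampling one to the other would manufacture
spatial precision neither has.

### Monte Carlo uncertainty propagation

Two simulations per site, 10,000 iterations each:

* **ACD only** — every cell keeps its most-probable class (deterministic);
  only the ACD draw varies.
* **ACD + classification** — each cell's class is redrawn from its
  probability vector at every iteration.

In both, each cell's ACD is drawn uniformly with replacement from the
empirical site-class distribution of 500 m values (empirical resampling
rather than a fitted density: it adds no distributional assumption). Draws
are independent across cells and iterations — no spatial error model; the
simulation is conditional on the mapped spatial pattern, which is exactly the
point of using it instead of a geostatistical model. The iteration statistic
is the mean ACD over the site's cells; runs are summarized by the mean and SD
of the 10,000 iteration means, and two runs are compared by mean difference,
SD ratio and the overlap of their iteration distributions. One RNG stream
per simulation, consumed in a fixed order (class draws first,
iteration-major; then ACD draws grouped by class), makes a run exactly
reproducible from its seed.

The characteristic behaviour — with confident probabilities the two modes
agree; with logged/burned confusion the mixed mode has a *lower* mean
(because burned carbon mixes into logged predictions) and a larger SD — is
asserted by the test suite on the synthetic fixture.

## What the synthetic generator emulates — and what it does not

`generate_landscape()` builds, per site: an intact canopy as a spatially
correlated Gaussian field (FFT convolution with a Gaussian kernel;
correlation length 8 px, SD 0.04 EVI around a 0.55 base); logged forest as
that field overlaid with low-EVI road lines (spacing 40 px, width 2 px,
depth 0.25 EVI) and square log decks at crossings; burned forest as the
field minus a 0.15 EVI depression plus fine-grained speckle (SD 0.06). The
magnitudes are calibration knobs chosen once to make the class signatures
qualitatively right (roads raise local contrast/entropy; fire lowers local
mean) — they are not estimates of any real site. Disturbed classes occupy
contiguous column bands snapped to the 500 m block quantum, emulating the
tens-of-hectares contiguous events of real reference polygons; each band is
split into four event polygons whose years are uniform on
[image year − 8, image year], so the five-year training filter always has
something to do. The polygons rasterize back to the class map exactly, by
construction and by test.

Plot ACD is drawn per 50 m plot from the class's (mean, SD) normal truncated
at zero by rejection — carbon density cannot be negative, and the burned
class's large SD (35 Mg C ha⁻¹ around 57.9) makes naive draws go negative.
Two regimes are bundled: a low-biomass regime (intact 89.2 ± 10.2, logged
93.9 ± 16.3, burned 57.9 ± 35.0 Mg C ha⁻¹) and a high-biomass regime (intact
185.3 ± 31.9, logged 156.8 ± 26.0, burned absent — exercising the donor
substitution).

One numerical consequence is worth stating precisely: block-median
resampling recovers the *median* of a class's plot distribution. For the
near-symmetric intact and logged classes this equals the mean, but zero
truncation skews the burned class, whose 500 m values center on the
truncated-normal median (≈ 60.1 for 57.9 ± 35) rather than the nominal mean.
The recovery tests therefore target the closed-form truncated median; on
real, untruncated lidar data the distinction does not arise in this form,
but any strongly skewed plot distribution will show the same median-vs-mean
gap after median resampling.

The generator does **not** emulate: atmospheric effects, clouds or haze;
sensor noise or co-registration error; gradual regrowth trajectories or
multi-date series; fragmentation and edge effects; spatially correlated
carbon error. Passing tests on the fixture therefore demonstrates that the
pipeline's logic and arithmetic are right and that its statistical behaviour
follows the intended mechanisms — not that the classifier would reach the
same accuracy on real imagery, where class signatures are far less
separable.

### The three-site study fixture

`make_multisite_fixture()` mirrors a three-site design: a mixed
logging-and-fire site and a burn-only site in the low-biomass regime, and a
logging-only site in the high-biomass regime with no local burned-forest
carbon (its burned ACD must be substituted from the other two sites). Desk
scale is 960 × 960 px (3 × 3 km) per site with 48 px (150 m) classification
cells, an 11 px texture window and 16 gray levels, 10 ensemble partitions and
2,000 Monte Carlo iterations — sizes chosen so a complete run finishes in a
few minutes on one CPU while every stage still has hundreds of cells to work
with. The full-scale defaults (45 px window, 32 levels, 180 px cells, 100
partitions, 10,000 iterations) remain the package defaults and are exercised
on small rasters in the unit tests.

## Degenerate inputs and tie-breaks, collected

* constant raster → quantizes to a single level; contrast 0, homogeneity 1,
  correlation 0 by convention;
* all-masked raster or window → error, or nodata at the caller's level;
* purity ties → burned > logged > intact, everywhere a tie can occur
  (labels, hard classification, majority aggregation);
* zero-SD features → standardized to 0, not NaN;
* zero-SD ACD parameters → point mass at the mean;
* probability rows must sum to 1 within 1e-6, checked before simulation;
* singleton strata → training half.

## Known limitations

* Raster I/O is the plain-text ESRI ASCII grid (exact double round-trip);
  map projections and GeoTIFF tags are out of scope — all geometry is pixel
  row/col space, which is sufficient for the grid-local science here.
* Per-site standardization uses all cells (see above).
* The donor-substitution default pools *all* other sites holding the class;
  with sites in very different biomass regimes a caller should restrict
  `donors` explicitly (the run manifest records what was pooled).
* The Monte Carlo model treats cells independently; it quantifies sampling
  uncertainty conditional on the map, not spatially correlated error.
* Accuracy CIs use the binomial normal approximation; for very small test
  sets an exact interval would be preferable.
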