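---
title: "Terrain health and contamination mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terrain health and contamination mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(terrapatch)
```

## The problem

Urban green spaces affect the health of the people living around them, but
keeping an up-to-date picture of where grass is thriving, drying out, or
buried under garbage is expensive at city scale. Satellite vegetation
indices (NDVI and friends) quantify greenness but, at meters per pixel,
cannot see a plastic bag or a pile of bottles. Low-altitude drone imagery
can: at roughly 30 m above ground a typical small-drone camera resolves
about 1.31 cm per pixel, enough to spot individual litter items.

terrapatch implements the full analysis chain for such imagery:

1. **Tiling** — large georeferenced RGB frames are cut into square patches
   (200 × 200 px by default) on a regular grid; each patch is the unit of
   classification and of area accounting.
2. **Taxonomy** — every patch belongs to one of eight classes: a health
   component (healthy `H`, dry `D`, unhealthy `UNH`, no vegetation `NV`)
   crossed with a contamination flag (suffix `C`).
3. **Classification** — a small convolutional network maps each patch to a
   class.
4. **Map statistics** — per-class patch counts become ground areas (via the
   ground sampling distance), a biomass percentage, and a contamination
   percentage, rendered as a color-coded cell map.

## Area accounting

The ground sampling distance (GSD) is the ground length of one pixel. A
square tile of side $t$ pixels covers $(\mathrm{GSD}\cdot t)^2$ square
meters; at the default profile $(0.0131 \cdot 200)^2 = 6.8644$, rounded to
6.86 m². All area accounting multiplies patch counts by this rounded
per-tile constant, which is what makes per-class area tables exactly
reproducible from count tables; the unrounded footprint is available via
`tile_footprint_area(digits = )`.

Two derived percentages summarize a terrain. *Biomass* is the share of
tiles whose class has a vegetation component — `H`, `D`, `UNH` and their
contaminated variants — over all tiles; a contaminated lawn still holds
biomass, which is why the `C` variants count. *Contamination* is the share
of tiles in any `C` class. Vegetated (`biomass`) and non-vegetated
(`NV` + `NVC`) tiles partition the grid, so the biomass percentage and the
non-vegetated percentage sum to 100 up to rounding.

```{r}
counts <- stats::setNames(c(2677, 7917, 376, 5270, 5, 162, 247, 146),
                          class_codes())
terrain_summary(counts)
```

These definitions were fixed by checking them against the bundled survey
count tables (`green_surveys()`): biomass-including-contaminated is the
reading under which the published per-campaign biomass figures follow
exactly from the label counts for three of the four campaigns. The fourth
campaign's reported biomass (47.34 vs 49.44 computed) and all of the
reported contamination percentages are **not** derivable from the printed
counts — they were produced by running a trained model over the complete
maps rather than over the labeled subset — so the package documents its
formulas and does not attempt to curve-fit those cells.

## Georeferencing

Tile centers are georeferenced under a local equirectangular
approximation, assuming north-up nadir imagery: metric offsets from the
image center are divided by 111,320 m per degree of latitude, with
longitude additionally scaled by $\cos(\mathrm{lat})$. Over the few
hundred meters a drone frame covers, the error of this approximation is
far below the tile size. Heading is not modeled; imagery is assumed
north-up, and EXIF GPS metadata is used when present but never required —
the whole pipeline runs in pure grid coordinates otherwise.

## The classifier

The classifier is a convolutional feature extractor plus a multilayer
perceptron head, implemented in vectorized base R (im2col convolutions,
2×2 max pooling, Glorot initialization, Adam, softmax cross-entropy):

* three conv blocks of 32, 64 and 128 filters (3×3 kernels, ReLU, each
  followed by 2×2 max pooling),
* a fully connected 128-unit ReLU layer,
* a fully connected 8-unit output layer with identity (linear) transfer;
  probabilities come from a softmax applied at prediction time, folded
  into the cross-entropy loss during training.

The default `training_config()` is batch size 20, 200 epochs, Adam at
learning rate 1e-2, no regularization. Two readings of an "iteration"
budget are supported: `epochs` counts full passes (the default
interpretation), while `max_steps` caps raw optimizer steps for the
literal mini-batch reading. Inputs are scaled to [0, 1]; no augmentation
or class reweighting is applied by default (reweighting is available via
`class_weights = TRUE` for heavily imbalanced manifests).

Adam at 1e-2 is an aggressive rate for conv nets and can diverge on small
datasets; all of the package's own experiments therefore run at 1e-3,
which we found uniformly stable, while 1e-2 remains the shipped default
configuration. Training is bit-reproducible: initialization and per-epoch
shuffling derive from `config$seed`, and all computation is
single-threaded deterministic R.

Retraining (`retrain()`) warm-starts from a fitted model's parameters —
no reinitialization — and continues on a new manifest. The Adam moment
estimates are deliberately reset: with a few hundred new tiles the stale
curvature estimates of the old terrain are more misleading than helpful,
and a fresh optimizer state keeps the retraining contract simple
(parameters are the only thing carried over).

## Synthetic scenes

Real campaign data is large and external; the package instead ships a
deterministic synthetic generator used by every downstream test. Each
health class gets a band-limited correlated-noise texture (smoothed
uniform fields) with the class's color statistics: green-dominant for
`H`, yellow-brown for `D`, a patchy green/brown blob mixture for `UNH`
(deliberately overlapping both neighbours, mirroring the confusion
structure seen in real campaigns), and low-saturation gray for `NV`.
Contaminated variants overlay 3–10 small convex high-contrast polygons
("litter", mostly white with occasional saturated plastic colors), each
under 5% of the tile, drawn from a separate random stream so that a
contaminated tile equals its clean counterpart outside the litter mask.
Total litter coverage is drawn between 8% and 18% of the tile.

Parameters were chosen once so that classes are separable but not
trivially so: the test suite asserts that a nearest-centroid classifier
on tile-mean RGB already exceeds 70% accuracy (so the textures carry
class signal), while leaving genuine work for the convolutional model,
which is held to ≥ 90% held-out accuracy under the experiment profile
below. Scene generation is seeded hierarchically —
one master seed, per-tile seeds derived from grid position — so any cell
can be regenerated independently.

What the generator does **not** emulate: real lighting and shadow,
perspective and lens distortion, seasonal variation, mixed-content tiles,
label noise, and the long-tailed appearance diversity of real litter.
Passing the synthetic acceptance experiments therefore demonstrates that
the pipeline's mechanics (tiling, training, evaluation, area accounting)
are correct and that the model can learn texture classes with litter
overlays — not that the architecture reaches any particular accuracy on
real field imagery.

## Experiment profile and problem sizes

The package's reference experiments (test suite and `scripts/acceptance.R`)
run at 32 px tiles with the default architecture, Adam 1e-3, batch 20:

* training: 640 balanced tiles (80 per class), 25 epochs;
* held-out evaluation: 160 seed-disjoint tiles (20 per class);
* end-to-end map check: a 12 × 14 scene, predicted biomass within ±2
  percentage points of ground truth;
* retraining: 600/120 tiles from a second, imbalanced terrain
  (contaminated classes at 2–5%), 10 epochs, held-out accuracy within 10
  points of the first terrain's.

These sizes keep a full run in the low minutes on one CPU core while
remaining large enough that the accuracy bars are meaningful; they are
the package's standing reference conditions, not tuning knobs.

## Numerical and design notes

* **Edge handling**: partial tiles at the right/bottom edges are
  discarded, not padded — published campaign tile counts imply whole
  tiles only.
* **Tile order**: row-major from the top-left, 0-based indices.
* **Degenerate metrics**: metrics on an empty confusion matrix, or with a
  zero denominator, raise errors rather than silently returning 0, so
  degenerate evaluations surface in tests.
* **Two accuracies**: the macro-averaged per-class binary accuracy
  (`macro_accuracy()`) and the conventional trace/total accuracy
  (`overall_accuracy()`) are both reported; they coincide only for
  diagonal matrices or two classes, and campaign-style "accuracy =
  precision = recall" statements correspond to the micro/trace reading.
* **Prediction ties** break toward the lowest class index in canonical
  order (`which.max` semantics); with continuous logits ties are
  measure-zero but the rule keeps prediction deterministic.
* **Splitting** is stratified by class whenever every class has at least
  two records, because a plain 9% random draw can miss the rare
  contaminated classes entirely; it falls back to a plain draw otherwise.
* **Class colors** (maps): H dark green, D yellow, UNH orange, NV gray;
  contaminated variants are the same hue darkened 40%. Any injective
  palette can be supplied to `render_map()`.
* **Train/test sizes** are manifest-driven parameters, not constants:
  published campaign descriptions disagree internally about the exact
  split (9001/901 vs 9000/901 of a 9901-label set), so the package takes
  `test_count` as an argument.
* The `NVC` class appears under the header "HVC" in some published count
  tables; the package treats that as a typographical variant of `NVC`,
  which is the code the class definitions actually produce.

## Known limitations

The classifier trains on CPU in R; it is sized for hundreds-to-thousands
of patches, not for the >100k-tile datasets of a production campaign.
JPEG EXIF parsing covers the GPS IFD only. The equirectangular
georeference ignores heading and terrain relief. Orthomosaic stitching of
overlapping frames is out of scope: every source image is tiled
independently, and duplicate coverage between overlapping frames is not
deduplicated.
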