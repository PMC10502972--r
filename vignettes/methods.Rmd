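---
title: "Methods: automated choroid segmentation and SfChT measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated choroid segmentation and SfChT measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`octchoroid` implements an end-to-end pipeline for measuring subfoveal
choroidal thickness (SfChT) on optical coherence tomography (OCT) B-scans,
together with the longitudinal statistics used to analyse SfChT in a
two-arm myopia-control trial (DIMS defocus spectacle lenses vs. single-vision
controls). The pipeline has five stages:

1. **Phantoms** — synthetic layered B-scans with pixel-perfect ground truth,
   so every downstream stage is testable without clinical data.
2. **Networks** — two encoder-decoder segmentation CNNs (a batch-normalized
   U-Net and a residual encoder-decoder) whose bottleneck is a
   strip-pooling block, plus late fusion by probability averaging.
3. **Training / evaluation** — dice-loss optimization with Adam and online
   augmentation; evaluation with the Dice similarity coefficient (DSC) and
   the average symmetric surface distance (ASSD).
4. **Post-processing** — 0.5 binarization, largest connected component,
   Otsu-based fovea localization, per-column thickness extraction and
   6-scan SfChT averaging.
5. **Cohort statistics** — a seeded simulator of the two-arm visit schedule
   and the analyses: change from baseline, baseline-adjusted group
   contrasts, Pearson associations, hierarchical multiple regression.

All array work is done in base R matrix algebra (the CNN engine included);
standard image operations (connected components, hole filling, Otsu
thresholds, rotation) use EBImage, and tabular results are tibbles with
`tidy()`/`glance()`/`autoplot()` methods.

## The synthetic phantom

A phantom is a stack of horizontal bands with integer boundary rows:
dark vitreous (intensity 0.05), a bright retinal band (0.60) whose per-column
thickness profile carves a Gaussian foveal pit, the brightest thin RPE line
(0.95), a medium choroid band (0.35) optionally containing darker elliptical
lacunae (0.12), and a dim sclera (0.15). Only the intensity image receives
multiplicative speckle noise (clipped to [0, 1]); the ground-truth choroid
mask is drawn from the integer boundaries, so its per-column thickness equals
the generating profile *exactly* — a requirement for using the phantom as a
metric oracle.

The band intensities are chosen so that an Otsu threshold on the central
columns separates the retina + RPE (≥ 0.6) from everything else (≤ 0.35):
the per-column foreground count is then a retinal-thickness proxy whose
minimum marks the foveal pit.

Defaults: a Spectralis-like 496×768 geometry and a 64×96 `"tiny"` preset for
CPU-scale training and tests. The axial pitch defaults to 3.87 µm/pixel, a
typical spectral-domain OCT value; the source study reports no resolution or
pitch, so these are conventions of this package, not reproductions. Scan
sets emulate the clinical acquisition of three horizontal plus three
vertical line scans, with a small seeded integer jitter of the choroid
profile per scan.

What the phantom does **not** emulate: physically realistic OCT speckle
statistics, light propagation, vessel shadowing, motion artifacts, or 3-D
volume scans. Passing tests on phantoms therefore demonstrate the internal
consistency of the pipeline (segmentation → fovea → thickness), not clinical
accuracy on real OCT images.

## Networks

Both architectures map a single-channel image to a per-pixel choroid
probability via a final logistic squashing (one output channel; binary
task):

* **U-Net**: `depth` encoder stages of two 3×3 conv + batch-norm + ReLU
  blocks with 2×2 max pooling, a bottleneck, and a mirrored decoder with
  nearest-neighbour upsampling and skip concatenations.
* **Residual encoder-decoder**: a ResNet-style encoder (identity-shortcut
  residual blocks per stage) with the same decoder. A classifier backbone
  alone cannot emit dense masks, so the decoder is a declared convention of
  this package.

The **strip-pooling bottleneck** replaces the deepest stage: feature maps
are average-pooled along entire rows (1×W) and columns (H×1), each strip is
mixed by an edge-padded 1-D convolution, the two maps are broadcast back and
summed, passed through a 1×1 convolution and a sigmoid, and the resulting
gate multiplies the identity path. This grows the receptive field along
whole image rows and columns — the natural axes of layered OCT anatomy.
Edge (replicate) padding in the strip convolutions was chosen so a constant
feature map stays exactly constant through the block, which keeps the block
well-behaved on uniform regions and testable in closed form.

**Fusion** is the elementwise mean of the two models' probability maps.
Whether scores should be averaged before or after the sigmoid is ambiguous;
probabilities are averaged here (the fusion then stays inside the two
inputs' range, and fusing a model with itself is exactly the identity).

The `"tiny"` preset (8 base channels, depth 2, ~28k parameters) is the test
and demo target; the `"full"` preset (64 base channels, depth 4, tens of
millions of parameters) is buildable but not exercised routinely.

## Training

Dice loss `1 − (2Σpy + s)/(Σp + Σy + s)` with smoothing constant `s = 1`
(standard stabilization; added to numerator and denominator) is minimized
with Adam (β₁ = 0.9, β₂ = 0.999). Augmentation follows the usual online
recipe: rotations within ±10°, random horizontal flips, brightness/contrast
jitter. On single-channel data a saturation jitter is undefined and is
deliberately a no-op. The geometric transform is shared by image and mask;
the mask is resampled nearest-neighbour and stays strictly binary; rotation
fills exposed image borders with the vitreous (background) intensity and the
mask with 0.

Hyperparameter defaults — learning rate 0.01, batch size 5, 20 epochs —
were fixed once by pilot convergence runs on tiny phantoms. Training is
fully seeded: the same `train_config(seed=)` reproduces identical loss
histories and weights.

Because minibatches are small and photometrically jittered, batch-norm
running averages drift from the statistics of clean images; after the last
epoch the running statistics are therefore re-estimated by a few
un-augmented, high-momentum calibration passes over the training images.
This closes the train/inference gap that otherwise costs several DSC points.

## Metrics

* **DSC** = 2|X∩Y| / (|X|+|Y|) over foreground pixel sets. Two empty masks
  score 1 by convention (documented); this case cannot arise in evaluation
  because ground-truth phantom masks are non-empty.
* **ASSD**: surface points are foreground pixels with at least one
  4-neighbour background pixel (image borders count as background);
  distances are Euclidean between pixel centres. The paired formulation
  (1/N)Σ(dᵢ + dᵢ*) is ill-defined when the two surfaces have different point
  counts, so the standard symmetric form (Σdᵢ + Σdⱼ*)/(N₁+N₂) is the
  default; a `paired = TRUE` variant exists for equal-size surfaces.
  An empty mask has no surface and is rejected.

Both metrics are verified against brute-force oracles (explicit set
counting; all-pairs nearest distances) on a thousand seeded random masks.

## Post-processing and SfChT

Probability maps are binarized at 0.5 (inclusive: p = 0.5 is foreground,
documented). Only the largest connected component is retained
(8-connectivity by default; exact ties broken toward the component whose
first pixel is smallest in (row, column) order) and enclosed holes — e.g.
choroidal lacunae — are filled, so per-column thickness can be counted as
foreground pixels × axial pitch. Counting pixels rather than subtracting
boundary rows is equivalent for simply-connected columns and robust once
holes are filled.

The fovea is located within the central 25 columns (A-scans): Otsu
thresholding isolates the bright retinal band, the per-column foreground
count proxies retinal thickness, and the minimum-count column is the fovea.
"25 pixels at the middle" is read as 25 central columns, since the search is
lateral; an even-width image centres the band one column to the left. Ties
(a perfectly flat retina) break toward the image centre; a constant central
band makes Otsu degenerate and is rejected. When a choroid mask is
available, counting is restricted to rows above the choroid's top boundary,
which decouples the retinal proxy from choroidal structure.

SfChT is the thickness at the fovea column, averaged over the available
scans (clinically six: 3 horizontal + 3 vertical). Scans whose subfoveal
column has no choroid foreground are excluded with a warning; measurements
are reported in µm (written to CSV with 2 decimals).

## Cohort simulation and statistics

The simulator draws a two-arm cohort on the trial's visit schedule
(baseline, 1 week, 1, 3, 6, 12, 18, 24 months). Its defaults are the study
conditions where printed: 78/80 subjects, baseline SfChT 280.95 (54.30) vs.
259.53 (49.36) µm, adjusted changes +6.75/−3.17 µm at 1 week,
+8.58 µm (DIMS) at 1 month and +13.64/−9.46 µm at 12 months. Visits without
a printed value are interpolated smoothly between those anchors
(`default_visit_changes()`); the per-visit noise SD of 13.5 µm back-solves
the printed 1-week SEM (≈ 1.52 µm at n = 78). Noise is Gaussian and
homoscedastic.

Axial length is generated 6-monthly: the 12-month elongation follows a
linear model on age, gender and the subject's *3-month* choroid change
(coefficient −0.0035 mm/µm), the other visits use the concurrent choroid
change with the same negative coefficient — so choroidal thickening and
axial elongation are negatively associated throughout, mirroring the
direction of the clinical association. Spherical equivalent change is
−1.8 D/mm of elongation plus noise. These magnitudes are package choices
calibrated to produce standardized effects of the same order as the
published regressions; they are not fitted to data.

Analyses:

* `change_from_baseline()` — per-subject visit-minus-baseline differences;
  subjects without a baseline are excluded with a warning.
* `adjusted_group_change()` — per-visit least squares of change on group +
  centred baseline covariate, reporting covariate-adjusted group means ±
  SEM. With identical baselines the covariate is void and raw means are
  returned. This per-visit contrast deliberately stands in for the trial's
  omnibus mixed between-within ANOVA, which is routine package inference
  and out of scope here.
* `pearson_r()` — validated sample correlation.
* `hierarchical_regression()` — Model 1: age + gender; Model 2: + one
  short-term choroid change. All variables (outcome included) are z-scored
  after coding gender 0/1, so coefficients are standardized betas; R²,
  ΔR² and two-sided coefficient p-values are reported (the significance
  flags are informational and never drive control flow).

## Numerical choices and degenerate inputs

* Thickness profiles are integers in pixel space; µm values are exact
  multiples of the axial pitch.
* `binarize()` is inclusive at the threshold; `largest_component()` of an
  empty mask is empty; tie-breaks are deterministic and documented.
* Weight initialization is seeded He-normal; every stochastic routine takes
  an explicit seed, and pipeline stage seeds are derived deterministically
  from one global seed, making the tiny end-to-end demo byte-reproducible.
* Gradients of every layer (convolution, batch norm, pooling, upsampling,
  strip pooling) are validated against central finite differences in the
  test suite.

## Problem sizes used in the test suite

The shipped tests and the acceptance script run at desk scale, a deliberate
package choice: 64×96 phantoms, 30 training / 10 evaluation images,
20 epochs (about a minute per training run), 20 phantom scan-sets for the
manual-vs-automated comparison, and 200 replicated cohorts of 158 subjects
for the statistical properties. The `"full"`-scale network is constructed
and parameter-counted but not trained in the suite.

## Known limitations

* Phantom realism is intentionally minimal (see above); reported DSC/ASSD
  on phantoms are not comparable to clinical performance figures.
* The residual branch's decoder, output channel count and input
  normalization are conventions; the source architecture is underspecified.
* No sub-pixel boundary interpolation, ETDRS-grid regional thickness or
  choroidal volume maps.
* The cohort simulator is a parametric stand-in, not a re-analysis of trial
  data; its unprinted visit effects and AL-model coefficients are package
  choices.
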