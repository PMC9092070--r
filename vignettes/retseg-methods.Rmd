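---
title: "Quantitative retinal morphometry with an attention-augmented U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative retinal morphometry with an attention-augmented U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retseg)
```

## The problem

Early retinal neurodegeneration — as in the monosodium-glutamate (MSG) mouse
model of metabolic syndrome — shows up in HE-stained sections as subtle
thinning of the inner plexiform (IPL), inner nuclear (INL) and nerve fiber
(RNFL) layers and as loss of ganglion cells. These changes are hard to score
by eye. retseg implements a quantitative alternative: segment each section
into six classes (Background, ganglion CELL, INL, IPL, OPL, RNFL), then reduce
the segmentation to ten morphometric parameters per section — layer areas
$S_R, S_{IPL}, S_{INL}, S_{OPL}$, ganglion-cell count $A$ and total area
$S_A$, and mean thicknesses $H_R, H_{IPL}, H_{INL}, H_{OPL}$ — and compare
groups with percent-of-control one-way ANOVA.

## The segmentation model

The segmenter is a fully convolutional U-Net. The encoder follows a VGG
skeleton: stages of 3×3 same-padding convolutions (batch-normalized, ReLU)
separated by 2×2 stride-2 max pooling, producing feature maps at exactly five
scales (the input resolution and four twofold downsamplings). The decoder
mirrors it with 2×2 stride-2 transposed convolutions, concatenating each
upsampled map with the same-scale encoder map (U-shaped skip connections)
before further convolutions, and ends in a 1×1 convolution to six per-class
score planes at full resolution. Same padding means the output label map has
exactly the input's frame, which the morphometry requires.

After every encoder stage a **Spatial Group-wise Enhance (SGE)** attention
block is applied. Per channel group, SGE pools the group globally to a
descriptor $g$, forms the position-wise similarity $c_p = x_p \cdot g$,
standardizes $c$ over positions, applies a per-group affine
$a = \gamma \hat c + \beta$, and multiplies the features by
$\sigma(a)$. The block adds exactly $2 \times \text{groups}$ parameters per
stage. Design choices the source left open, fixed here:

* standardization uses an $\varepsilon = 10^{-5}$ variance guard;
* the affine initializes to $(\gamma, \beta) = (0, 1)$, so an untrained block
  is the constant gate $\sigma(1) \approx 0.731$ — a closed form the tests
  exploit;
* SGE follows *every* stage (the source says only that the module "was
  added"); `sge_enabled = FALSE` gives the plain U-Net baseline;
* `sge_groups` defaults to 8 (no group count is published);
* ReLU nonlinearities and per-convolution batch normalization are standard
  VGG/U-Net practice and are assumed, not published.

No deep-learning framework exists in this R environment, so the network —
forward passes, full backpropagation (verified against finite differences to
~1e-8 relative error) and the Adam optimizer — is implemented in base R on
BLAS matrix products. Convolutions are im2col gemms; everything is double
precision and bit-deterministic for a fixed seed.

## Training regimen

Defaults mirror the published regimen: Adam, batch size 4 (implemented as
gradient accumulation over single-image forward passes, so batch
normalization uses per-image spatial statistics), initial learning rate
0.001, and an exponential decay interpreted multiplicatively — during epoch
$e$ the rate is $0.001 \times 0.92^{e/\text{step}}$ with step 1. Augmentation
reproduces the published menu (horizontal flip with probability 0.5, scaling
in [0.5, 1.5] with center crop/pad back to frame, HSV color jitter, rotation
0–15° filling exposed corners with Background); geometric transforms hit
image and labels identically, labels resampled nearest-neighbour only. The
published magnitudes of the HSV jitter are not stated; we default to hue
±0.03 and saturation/value ×[0.8, 1.2].

The loss is per-pixel multi-class cross-entropy (the source does not state
its loss). Class-frequency weights are exposed in `train_config()` because
the CELL and OPL classes occupy few pixels; the desk-scale smoke test uses
weights (0.5, 3, 1, 1, 2.5, 1) to keep those classes from being swamped.
"Unfreezing" of a pre-trained VGG-16 backbone is out of scope — training is
end-to-end from He-normal initialization; a pre-trained-weights hook would
slot into `seg_model()` but is deliberately absent so the package builds
offline.

## Morphometry

The post-segmentation chain is: per-class binarization (label equality, or
`>= 0.5` on probability maps), morphological opening (`erosion_iters`
erosions then equal dilations, 3×3 square element by default), 8-connected
component analysis, and small-object filtering. Operational definitions the
source leaves informal, fixed here:

* **Mean thickness** $H_X$ is the mean per-column vertical pixel count over
  columns the layer occupies. Sections are oriented vitreous-side-up, so
  columns cross layers perpendicular to their run; a vertical sinusoidal
  displacement of a constant-thickness band leaves $H$ exactly unchanged,
  which the tests assert. A medial-axis-normal thickness is out of scope.
* **"A certain threshold"** for layer domains defaults to 0.1% of the image
  pixels, configurable.
* **Cell counting**: components that vanish under `erosion_iters` erosions
  are discarded as specks; each survivor contributes
  $\max(1, \min(\mathrm{round}(r), \texttt{max\_split}))$ cells, where $r$ is
  the bounding-box aspect ratio $\max(w,h)/\min(w,h)$ and splitting engages
  at $r \ge 1.8$ — elongated domains are adherent clumps. Rounding is half
  away from zero. $S_A$ is measured on the *original* components, so the
  erosion filter does not bias areas.
* Conventions stated once and used everywhere: 8-connectivity, 0-based
  row/column indexing, half-open bounding boxes.

With `erosion_iters = 0` and `min_layer_area_frac = 0` the whole chain is the
identity on a clean label map — the acceptance suite checks that the profile
of a generated ground-truth label map equals the generator's recorded truth
on all ten parameters exactly.

## The synthetic world

`generate_section()` draws a stated world, not a tuned one: horizontal bands
stacked RNFL → CELL row → IPL → INL → OPL over background, sharing a
sinusoidal column displacement; ganglion cells as filled ellipses on the
RNFL/IPL boundary, a configurable fraction fused into adherent clumps of 2–4;
background-labeled vacuoles punched into IPL/OPL; an HE-like palette (pinks
for plexiform layers, purples for nuclear classes — the source publishes no
color priors, so these are free parameters); Gaussian pixel noise and blur
applied to the RGB rendering only, never to labels. The `msg_like` condition
multiplies IPL and INL thickness by 0.6, RNFL by 0.7 and the cell count by
0.6 — the qualitative phenotype contrast reported for MSG mice (significant
IPL/INL thinning, reduced ganglion cells) with OPL left untouched so a null
parameter exists. Cohorts add per-section lognormal jitter with CV 0.08,
a realistic between-animal variability for murine retinal layer thickness.

One geometric choice deserves emphasis: cell centers snap to the pixel grid
and radii to half-integers, so a planted clump of $k$ cells has bounding-box
ratio exactly $k + 2/(2R_x - 1)$ and a single cell at most $5/3$. The
aspect-ratio splitting rule therefore recovers planted multiplicities
*deterministically*, which is what makes an exact identity test on the cell
count possible at all; free-floating ellipse rasterization would put ratios
on rounding boundaries. The minimum cell semi-axis when clumps are enabled is
3 px for the same reason.

What the generator does **not** emulate: nuclear texture inside the INL,
stain variability and deconvolution physics, the outer retina (ONL,
photoreceptors) as separate classes, tissue folds and debris. A green test
therefore establishes that the pipeline's machinery is correct on layered
anatomy with known truth — not that the network would reach any particular
accuracy on real mouse tissue.

## Statistics

`one_way_anova()` is the classical fixed-effects decomposition
($F = \mathrm{MSB}/\mathrm{MSW}$, upper-tail $p$); it refuses degenerate
input (zero within-group variance) rather than reporting $p = 0$.
Percent-of-control sets the control-group mean to 100%. Stars follow the
caption convention ($p<0.05$ \*, $p<0.01$ \*\*, $p<0.001$ \*\*\*). The source
reports vs-control stars yet names an omnibus ANOVA; since it does not
disambiguate, `compare_profiles()` reports both the omnibus $p$ over all
groups and a per-group two-group $F$ vs control (for two groups they
coincide, and $F = t^2$). No multiple-testing correction is applied across
the ten parameters, mirroring the source; a Holm-adjusted column is emitted
alongside, clearly labeled as an extension.

## Numerical and scale choices

* Images must be divisible by 16 in both dimensions (four poolings);
  indivisible input is an error instructing padding, never silent cropping.
* Argmax ties break toward the lowest class id, so an untrained all-equal
  score map yields Background.
* The desk-scale defaults (reduced encoder widths, 64–128 px phantoms, a few
  epochs) exist so the full pipeline runs in minutes on one CPU; the
  published hyperparameters (100 epochs, widths up to 512, 3,000/500 split)
  remain reachable through configuration. The training smoke test uses
  widths (12, 24, 32, 48, 48), 40 sections of 128², 8 epochs — chosen once
  for capacity and budget, and it clears held-out MIOU 0.7 around epoch 4.
* The memorization sanity test relaxes the decay factor to 0.99: with one
  section and the published 0.92 decay, the total step mass
  $\sum_e 0.001 \times 0.92^e \approx 0.0115$ is exhausted before
  memorization completes. The schedule itself is pinned exactly by separate
  tests.
* Metric conventions: MPA/MIOU generalize the published binary formulas to
  $k$ classes (the per-class results table requires it); classes absent from
  the truth are excluded from MPA rather than scored 0, and a class absent
  from both prediction and truth has undefined IoU, reported as missing.
  Because the published per-class "PA" could be either one-vs-rest accuracy
  or recall, reports include both, labeled.

## Known limitations

* Pure-R training is CPU-bound; full-scale runs (3,500 images, 100 epochs,
  full VGG-16 widths) are configuration-reachable but not practical here.
* Batch normalization uses per-image statistics during training rather than
  cross-image batch statistics; with batch-size-4 accumulation this is a
  minor semantic difference, documented rather than hidden.
* The TIFF codec reads/writes uncompressed baseline RGB only (8/16-bit);
  16-bit input is rescaled by the documented rule `round(v/257)`.
* Label maps are stored as single-channel PNGs whose gray value *is* the
  class id (with a palette renderer for display); a palette-chunk indexed
  PNG writer is not implemented in the available stack.
* `pixel_size_um` is a free input: the source never links magnification to
  pixel size, so morphometry reports pixels unless a size is supplied.
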