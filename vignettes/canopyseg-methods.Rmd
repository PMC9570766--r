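---
title: "Mapping forest-pest canopy damage with canopyseg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forest-pest canopy damage with canopyseg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bark beetle attack and aspen leaf miner defoliation change a canopy's
chlorophyll content, leaf structure and water status. In optical
satellite imagery these changes surface mainly in the red-edge
(680–780 nm), near-infrared and shortwave-infrared bands — and more
sharply in ratio-type vegetation indices, which cancel the broadband
brightness variation (illumination, topography, canopy density) that
dominates the raw bands. canopyseg casts damage mapping as three-class
semantic segmentation of multispectral raster stacks: background (0),
bark beetle (1), aspen leaf miner (2), at 10 m ground sample distance.

## Feature stacks

A scene enters the pipeline as physical-scale surface-reflectance (or
12-bit DN) bands at a common resolution; `resample_band()` brings 20 m
and 60 m bands to 10 m by integer-factor nearest or bilinear resampling.
Twenty-one indices are registered: thirteen widely used ones (NDWI,
DWSI, NGRDI, RDI, GLI, NDRE2, PBI, NDVI, GNDVI, CIG, CVI, NDRE3, DRS)
and eight red-edge indices (ND790/670, NDVI690-710, NDRE, NDVI65,
GNDVIhyper, RENDVI1, RENDVI2, RI). Each index is computed on the
physical scale, then linearly stretched to 8-bit between its 2.5th and
97.5th percentiles (per band, per scene; values outside clip to 0/255)
so that extreme outliers cannot compress the usable range. Raw bands are
scaled directly by `round(v / 4095 * 255)`. Numerical choices:

* denominators with magnitude below ε = 1e-8 mark the pixel nodata
  rather than propagating ±Inf into the percentile statistics;
* DRS is the Euclidean distance `sqrt(B4² + B12²)` of the red and
  SWIR-2 reflectances;
* 8-bit values are stored as rounded integers and rescaled to [0, 1]
  before entering the network;
* the RGB selection is ordered B4, B3, B2 (true-colour convention);
* stretch percentiles use only non-nodata pixels, and a constant band
  stretches to all zeros with a warning.

Six channel selections are predefined (3, 11, 16, 24, 18 and 32
channels). The 18-channel set removes the red-edge material from the
32-channel set: bands B5–B7, the indices NDRE2, NDRE3 and CVI, and all
eight red-edge indices.

## Dataset construction

`grid_crop()` tiles a stack and its label raster on a regular
non-overlapping grid from the top-left corner (default 256 px, any
multiple of 32). Edge remainders are kept: the feature cube is
zero-padded and the label patch padded with an ignore value (255) that
is excluded from both the loss and the metrics — discarding border
tiles would bias against damage near scene edges. Tiles whose labels
are entirely ignore are dropped before splitting. `split_dataset()`
shuffles tile ids under a recorded seed and partitions 64/16/20
(validation and test counts are `round(f·n)`, the remainder trains); a
contiguous `"spatial"` mode is available to curb autocorrelation
leakage between the splits. Stores round-trip bit-for-bit through
`write_tiles()`/`read_tiles()`.

## The network

The model is a nested encoder–decoder. The encoder produces five
feature maps $X^{i,0}$ at strides 2–32; decoder node $X^{i,j}$
concatenates $X^{i,0..j-1}$ with the 2× bilinearly upsampled
$X^{i+1,j-1}$, applies a 3×3 convolution + batch norm + ReLU down to
the row width $w_i$, and finishes with the configured attention block —
the dense nested skip topology that lets fine-resolution rows see every
coarser reconstruction.

**Split-attention encoder.** Each encoder stage is a residual unit that
splits its 3×3 transform into `radix = 2` parallel branches, pools the
branch sum globally, passes it through a two-layer bottleneck gate, and
weights the branches by a per-channel r-softmax (sigmoid when
radix = 1) before fusing and adding the shortcut. Two encoders are
provided:

* `slim-split-attn` (default): one split-attention block per stage,
  emitting the decoder widths 16/32/64/128/256 directly — the printed
  stage widths taken literally, and the only variant trainable at CPU
  scale;
* `resnest101-projected`: a deep bottleneck trunk (3-conv stem, max
  pool, stage depths 3/4/23/3, output widths 128–2048, split-attention
  inside each bottleneck) followed by 1×1 lateral projections onto the
  decoder widths. This resolves the tension between pretrained-backbone
  widths and the printed decoder widths. `adapt_pretrained_stem()`
  converts published 3-channel first-layer kernels to C channels by
  tiling the RGB-mean kernel and rescaling by 3/C, which preserves the
  response to constant input exactly; remaining trunk weights copy
  verbatim. No weights ship with the package — the function is the
  adaptation contract, usable when a checkpoint is available locally.

**scSE attention.** At the end of every nested skip pathway: the cSE
arm squeezes globally, bottlenecks the channel vector (reduction 2),
and sigmoid-rescales channels; the sSE arm projects to one channel with
a 1×1 convolution and sigmoid-rescales pixels. The two rescaled maps
combine by element-wise maximum (addition available by configuration);
`cse`, `sse` and `none` variants support the ablation grid. A probe
mode forces every gate to 1, which makes all variants identical — used
as a structural test that the attention is purely multiplicative.

**Heads and deep supervision.** 1×1 convolutions with sigmoid
activation sit on $X^{0,1..4}$; each head's K = 3 channels are
renormalised per pixel to sum to one (the cross-entropy term needs a
distribution; softmax is available as the conventional alternative) and
bilinearly upsampled 2× to input resolution — the stem places $X^{0,0}$
at half resolution, standard for residual-family hybrids. The training
loss is the unweighted mean of the four per-head losses; the inference
map is the mean of the four head probability maps (or the deepest head
alone, by configuration), with ties in the argmax broken toward the
lower class index.

Normalisation is batch norm with momentum 0.1 throughout; weights are
He-normal initialised; everything runs on the package's reverse-mode
autodiff engine over `(H, W, N, C)` arrays, with convolution executed
as kh·kw shifted GEMMs (and the stride-1 input gradient as a
flipped-kernel convolution). Every operator's gradient is verified
against central finite differences in the test suite.

## Objective

$$L = 0.5\,L_{dice} + 0.5\,L_{sce}$$

* **Soft Dice**, per class: $1 - 2|X\cap Y|/(|X| + |Y| + \epsilon)$
  with $|X\cap Y|$ the element-wise product sum of the one-hot target
  and predicted-probability planes, macro-averaged over the three
  classes and accumulated at batch level — the macro average keeps the
  rare damage classes' gradients from being swamped by background.
* **Label-smoothed cross-entropy**: targets become
  $(1-\alpha) + \alpha/K$ on the true class and $\alpha/K$ elsewhere
  (α = 0.1, K = 3); the loss sums $-p_c \log(q_c + \epsilon)$ over all
  classes per pixel, averaged over non-ignored pixels. Summing over the
  full class vector (not only the true class) is what makes the α/K
  mass act as regularisation.
* ε = 1e-7 in denominators and logarithms; ignore pixels are excluded
  from both terms; mixture weights are configurable but default to the
  0.5/0.5 equal mix.

Note a structural consequence of smoothing: with α = 0.1 the
cross-entropy is bounded below by the smoothed-target entropy (≈ 0.291
nats), so the combined loss cannot fall below ≈ 0.146 no matter how
good the fit. Interpolation-capacity checks therefore run with α = 0,
where a perfect fit has exactly zero loss.

## Training

AdamW (β = 0.9/0.999, decoupled weight decay 1e-3), batch size 6, 300
epochs, under cosine annealing with warm restarts: within a cycle of
length $T_i$, $lr = lr_{min} + \tfrac12(lr_{init} - lr_{min})(1 +
\cos(\pi t/T_i))$ with $lr_{init} = 10^{-4}$, $lr_{min} = 10^{-5}$,
$T_0 = 2$ and $T_{mult} = 2$, so restarts fall at cumulative epochs 2,
6, 14, 30, 62, 126, 254. The schedule steps per batch at fractional
epoch resolution. After each validated epoch the validation mIoU is
computed with the same head combination used at inference, and the
highest-mIoU state is the returned model. No early stopping; divergence
(non-finite loss or loss > 1e4) aborts with the last finite state.
`run_ablation()` trains one cell per grid point (attention variant ×
decoder widths × band selection) under a shared seed and tabulates
test metrics with parameter counts.

## Evaluation

All metrics derive from a single K×K confusion matrix accumulated over
every evaluated pixel (micro aggregation — the convention behind
model-comparison tables; a per-tile average would weight small tiles
up). One-vs-rest per class: precision, recall, F1 (harmonic mean), IoU
$= TP/(TP+FN+FP)$; globally: accuracy (trace over total), mIoU
(unweighted class mean) and FWIoU ($\sum_c \text{freq}_c \cdot
\text{IoU}_c$ with true-class frequencies as weights). Denominator-free
classes report 0 with an `undefined` flag rather than NaN.

## Full-scene inference

`predict_scene()` crops the scene on the same regular grid
(zero-padding edges), predicts tiles in evaluation mode, writes each
prediction at its origin and crops the padding, so output dimensions
always equal input dimensions and, for exact multiples of the tile
size, the stitched map equals the independent per-tile predictions
pixel for pixel. No overlap averaging by default (an overlap mode
exists but plain grid stitching is the reference behaviour);
georeferencing metadata passes through untouched.

## Synthetic scenes: what they emulate and what they do not

`generate_scene()` builds seed-reproducible labelled scenes: elliptical
damage patches (random size, orientation, axis ratio; classes never
overlap) stamped on a healthy-forest background, with per-class
per-band mean digital numbers on the 12-bit scale. The default patch
density targets the damage coverage reported for the Skeena study
region — about 15% of the area affected by bark beetle and 10% by
aspen leaf miner — with beetle patches larger (radii 12–40 px) than
leaf-miner patches (8–30 px); counts scale with scene area so the
coverage fractions are scene-size invariant. Noise has two parts:

* a **shared multiplicative brightness field** (sd 10%, Gaussian-
  smoothed, σ = 3 px) multiplying every band identically — a stand-in
  for illumination, topography and stand-density texture; because it is
  common to all bands it cancels in ratio indices;
* **independent per-band noise** (sd 2%) that does not cancel.

The class spectra shift damage mainly in red-edge/NIR (down) and SWIR
(up), with visible-band shifts kept below one within-class standard
deviation. The emergent structure — raw-band class separation weak,
NDVI/NDWI/NDRE-type separation strong (≫ 3 within-class sd), the two
damage classes mutually distinct — is exactly the regime in which index
channels earn their keep, and it is what makes the pipeline's
directional property (full stacks beat RGB-only stacks) hold for the
right reason.

What the generator does **not** emulate: spatial texture beyond
smoothed Gaussian fields, mixed or graded damage pixels, cloud and
shadow, sensor PSF and co-registration error, phenology. Passing the
synthetic end-to-end tests therefore demonstrates that the machinery
learns and evaluates correctly, not that real-scene accuracies are
reproduced; real Sentinel-2 results additionally depend on label
quality and atmospheric correction, which are out of scope (the package
accepts already-corrected, co-registered rasters and raster labels).

## Desk-scale problem sizes

The shipped tests and the acceptance script exercise the pipeline at
sizes a laptop CPU handles in minutes, chosen once as the package's
reference experiment: two 320×320 (or 256×256) scenes, 64×64 tiles,
the slim encoder at widths 8/16/32/64/128, batch 6, and ~100–300 AdamW
steps. At these sizes the held-out mIoU lands around 0.75–0.8 against
an all-background baseline of ≈ 0.3, and the full-stack vs RGB-only
gap holds on every tested seed (≈ 0.56–0.74 vs ≈ 0.33–0.52 after 100
steps), so the qualitative conclusions do not ride on threshold
effects. The full-size configuration (256×256×24
cubes, widths 16–256, 300 epochs) is exactly what `model_config()` and
`train_config()` produce by default.

## Known limitations

* CPU-only: the autodiff engine is BLAS-bound; full-scale training
  (thousands of 256×256×24 cubes, 300 epochs) is out of desk reach.
* No data augmentation (none is part of the reference procedure).
* The deep pretrained-style encoder is structurally faithful but ships
  without weights; `adapt_pretrained_stem()` handles channel adaptation
  when weights are supplied.
* GeoTIFF georeferencing travels in a JSON sidecar rather than embedded
  TIFF tags (no GDAL binding is used).
* Mixed-damage pixels and overlap-averaged stitching are out of scope
  by design.
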