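# canopyseg

Semantic segmentation of insect-induced forest canopy damage — bark
beetle kill and aspen leaf miner defoliation — in Sentinel-2-like
multispectral imagery.

Bark beetles and leaf miners alter the internal chemistry and water
status of canopies before and beyond what true-colour imagery shows.
Those changes are most visible in the red-edge (680–780 nm), NIR and
SWIR bands and in ratio-type vegetation indices built from them. This
package implements a full pipeline that exploits that signal:

1. **Feature stacks** — the 11 usable surface-reflectance bands
   (B2–B12 without B1/B10) plus 21 registered vegetation indices
   (NDVI, NDWI, NDRE, CIG, DRS, … and 8 red-edge indices), each scaled
   or percentile-stretched to 8-bit. Six standard band selections are
   built in (3, 11, 16, 24, 18 and 32 channels); the default is the
   24-channel "11 bands + 13 indices" stack.
2. **Dataset** — regular-grid tiling into 256×256 (or any multiple of
   32) cubes, 64/16/20 train/validation/test splitting, persistent tile
   stores and split manifests.
3. **Model** — a nested encoder–decoder (UNet++-style dense skip
   pathways, decoder widths 16/32/64/128/256) over a split-attention
   residual encoder, with concurrent spatial and channel
   squeeze-and-excitation (scSE) attention at the end of every nested
   skip pathway and four deep-supervised 1×1-convolution sigmoid heads.
   The network runs on a package-internal reverse-mode autodiff engine
   (BLAS-backed; every operator gradient is finite-difference tested).
4. **Objective** — `L = 0.5 · L_dice + 0.5 · L_sce`: macro-averaged soft
   Dice (robust to the background/damage class imbalance) plus
   label-smoothed cross-entropy (α = 0.1, K = 3).
5. **Training** — AdamW (weight decay 1e-3, batch 6) under cosine
   annealing with warm restarts (T₀ = 2, T_mult = 2, lr 1e-4 → 1e-5),
   best-validation-mIoU checkpoint selection, and ablation grids over
   the attention variant, decoder widths and band selections.
6. **Evaluation & inference** — confusion-matrix metrics (per-class
   precision/recall/F1/IoU, accuracy, mIoU, FWIoU) and full-scene
   prediction by tile-and-stitch, exact to the pixel.
7. **Synthetic scenes** — a seeded generator producing labelled
   multispectral scenes whose class spectra separate weakly in raw bands
   but strongly in ratio indices, so the whole pipeline is testable
   offline.

## Worked example

```r
library(canopyseg)

# a labelled synthetic scene: 11 bands, beetle + leaf-miner patches
sc <- generate_scene(synthetic_spec(height = 320, width = 320, seed = 101))

# 24-channel 8-bit feature stack and 64-pixel training tiles
stack <- build_feature_stack(sc$scene, "bands11+13")
tiles <- grid_crop(stack, sc$labels, tile_size = 64)
split <- split_dataset(tiles, fractions = c(0.64, 0.16, 0.20), seed = 7)

# slim split-attention model, 300 AdamW steps on CPU
mcfg <- model_config(in_channels = 24, decoder_widths = c(8, 16, 32, 64, 128))
tcfg <- train_config(mcfg, seed = 3, max_steps = 300, epochs = 200)
fit <- train_model(tcfg, tiles, split)

evaluate_tiles(fit$model, tiles, split$test_ids)
```

The final call prints (one CPU, ≈5 minutes of training; numbers from
this exact seedset):

```
Segmentation metrics over 20480 pixels
 class precision recall    f1   iou undefined
    BG    100.00  92.89 96.31 92.89     FALSE
    BB     91.01  98.97 94.83 90.16     FALSE
   ALM     53.45 100.00 69.67 53.45     FALSE
accuracy 94.40%  mIoU 78.83%  FWIoU 90.69%
```

Per class: `BG` background, `BB` bark beetle, `ALM` aspen leaf miner.
IoU is intersection-over-union of the predicted and true pixel sets;
mIoU averages it over the three classes and FWIoU weights it by class
frequency — the headline numbers for damage-mapping quality. An
all-background predictor on the same tiles scores mIoU ≈ 0.3, so the
model is learning the damage classes, not just the majority class
(the low-precision ALM row is the smaller, rarer patch class — exactly
the behaviour surveys report for leaf-miner damage).

Full scenes are mapped with

```r
pred <- predict_scene(stack, fit$model, tile_size = 64)
evaluate_scene(pred, sc$labels)   # scene accuracy 0.934 here
```

A command-line interface over the same functions is installed at
`system.file("cli", "canopyseg.R", package = "canopyseg")` with
subcommands `synth`, `prepare`, `tile`, `split`, `train`, `ablate`,
`evaluate`, `predict` and `profile`.

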