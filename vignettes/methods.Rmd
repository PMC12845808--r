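---
title: "Static-camera preprocessing and dual-stream fusion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static-camera preprocessing and dual-stream fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pensight)
```

## The model

`pensight` implements an occlusion-aware detection pipeline for pigs filmed
by *fixed* cameras. A static camera makes two one-time, per-environment
preprocessing products possible:

1. **Background suppression (BIG).** Given the current frame and a clean
   background plate of the same pen, the per-pixel, per-channel absolute
   difference is collapsed to a single map by taking the channel maximum.
   Otsu's method thresholds that map; pixels whose binarized value is at
   least 128 keep their original color, all others are set to black. The
   result is a *background-suppressed image*: animals (things absent from
   the plate) survive, everything static disappears.

2. **Facility masking (FIG).** Pens contain bright fixed structures
   (feeders, pipes, rails) that occlude animals. From an 8-bit depth map of
   the empty pen (higher = closer to the camera), Otsu thresholding
   separates close structures from the floor, producing a binary facility
   mask. The *image fuser* paints facility pixels white, (255, 255, 255),
   in **both** network inputs, marking them as "known occluder" rather than
   letting them masquerade as animals.

3. **Dual-stream stem (BSI).** The detector consumes two co-registered
   views: the (optionally facility-masked) input frame and the suppressed
   image. Each view passes through its own stride-2 3x3 convolution. The
   suppressed branch is turned into an attention map: activation, then
   SoftMax across channels, then multiplication by a scalar
   `lambda_mult`. The attention map multiplies the input-branch features
   element-wise; the modulated map and the input-branch map are stacked
   along a new depth axis; a 3x3x3 convolution with stride (1, 2, 2) mixes
   them; max pooling over the depth axis collapses the pair. The stem maps
   `(B, 3, H, W)` pairs to `(B, C, H/4, W/4)` features, replacing a
   backbone's first convolution layer and halving every downstream
   feature-map resolution.

Everything downstream is standard: a small dense single-scale detector
(objectness + box regression on a stride-16 grid), greedy IoU matching,
precision/recall/F1, and all-point-interpolated AP50.

## Parameters, defaults, and why

### Scene generator (`scene_config()`)

| Parameter | Default | Rationale |
|---|---|---|
| `height`, `width` | 160 | Smallest size divisible by 4 (stem) and 16 (grid) that leaves ~10 px/cell; CPU budget. |
| `n_animals` | 3 | Enough box diversity per frame without heavy crowding at 160 px. |
| `animal_axis_range` | (9, 18) | Semi-axes giving 18–36 px animals: one to three grid cells, so box regression is learnable. |
| `animal_intensity` | mean 175, sd 18 | Pigs are brighter than a dirty floor but darker than metal facilities. |
| `background_texture` | scale 9, RGB (60, 72, 58), amp 10 | Low-frequency greenish-grey floor; blurred noise emulates bedding/ dirt patches. |
| `facility_layout` | one horizontal bar (y 30–44, 235) and one vertical bar (x 100–112, 215) | Emulates a feeding rail plus a ceiling pipe; bright and fixed. |
| `facility_depth_value` / `background_depth_value` | 220 / 40 | Strongly bimodal depth, as for ceiling-mounted structures over a flat floor. |
| `noise_std` | 3 | Mild sensor noise; keeps the background plate and frame from being trivially identical. |

The "unseen" configuration (`example_scene_config("unseen")`) changes the
floor color and texture scale (brownish, coarser) and moves/resizes both
facility bars. This is the desk-scale analogue of deploying the trained
detector in a different barn.

**What the generator emulates:** a static background with low-frequency
texture; bright occluding structures at closer depth; several elliptical,
speckled animal blobs drawn *beneath* the facility (facilities occlude
animals); paired clean background/depth plates; a seen-to-unseen
environment shift. **What it does not emulate:** animal motion and
contact/huddling, illumination change over time, perspective and lens
distortion, depth-sensor noise correlated with geometry, or photorealistic
texture. Conclusions drawn from it concern *mechanisms* (what each
preprocessing step contributes under an environment shift), not absolute
detection accuracy.

Problem sizes used in tests and the experiment (160x160 images, 16–24
training frames, tens of epochs) are our own choices driven by CPU budget;
they are study conditions, not tuned quantities.

### BSI stem (`bsi_config()`)

* `C = 16` stem channels — small enough for CPU training, wide enough that
  the channel SoftMax is meaningful.
* `lambda_mult = 2` — the attention mass; the ablation axis exposes 1x/2x/3x,
  with 2x the default.
* `activation = "silu"` — see design notes below.
* `softmax_axis = "channel"` — see design notes below.
* `fusion = "3dconv"` — the full method; `addition` and `concat2d` are the
  ablation baselines.

### Toy detector (`detector_config()`)

Single-scale stride-16 head emitting an objectness logit and four box
offsets per cell; binary cross-entropy with positive-cell upweighting
(`pos_weight = 2`) plus L1 box loss on positive cells (`lambda_box = 5`);
Adam with `lr = 2e-3`. The first ground-truth box to land in a cell claims
it. These are the simplest choices that make the detector trainable in
seconds per epoch while still ranking preprocessing variants.

## Numerical choices

* Images are plain integer arrays in [0, 255]; all differencing is done in
  double precision to avoid 8-bit wraparound, then clamped and rounded.
* Otsu's threshold maximizes between-class variance over all 256 candidate
  thresholds with cumulative sums (exact, no sampling); ties take the
  smallest threshold; a constant image returns its own value, yielding an
  empty foreground under the strict `> t` rule.
* Convolutions are im2col gathers feeding BLAS matrix multiplication, with
  analytic backward passes; gradient correctness is verified against
  central finite differences (observed errors ~1e-11 at 1e-5 step).
* FLOPs use `2 * prod(out_spatial) * Cout * (Cin / groups) * prod(kernel)`
  with double accumulation (the counts overflow 32-bit integers).
* Seeds: every stochastic routine takes an explicit seed; derived seeds use
  a fixed affine-mod scheme, and the global RNG state is saved and restored
  so library calls never perturb user streams.

## Design rationale for under-specified details

These points are stated loosely (or not at all) in the method description;
the package fixes them as follows:

* **Channel-max difference.** The per-channel absolute difference is
  collapsed by the per-pixel maximum over R, G, B before thresholding.
  Taking the max (rather than the mean or luminance) keeps an animal that
  differs from the background in only one channel detectable; it also makes
  the single-channel threshold well-defined.
* **The >= 128 mask convention.** Binarized maps are written as {0, 255}
  images; every consumer treats a pixel as "on" when its value is at least
  128. This makes masks robust to round-tripping through 8-bit image files
  and makes the midpoint behavior explicit (128 is "on").
* **SoftMax axis.** The attention SoftMax is taken across *channels* at
  each spatial location (the common channel-attention reading): at every
  pixel the suppressed branch distributes a mass of `lambda_mult` over the
  C feature channels, so attention reweights *what* is detected at a pixel
  rather than *where*. The spatial alternative is implemented
  (`softmax_axis = "spatial"`) as an ablation; with it, attention mass is
  spread over H x W positions per channel and vanishes as resolution grows,
  which is why it is not the default.
* **3x3x3 fusion kernel.** The depth axis has extent 2 (modulated, input);
  a depth kernel of 3 with padding 1 lets each output depth slice see both
  inputs while keeping the "conv 3D, stride (1, 2, 2), then depth max-pool"
  geometry stated for the stem. A depth kernel of 1 would reduce the stage
  to two independent 2D convs and break the cross-view mixing.
* **Stack order (modulated, input).** Only "stacked to 5D" is specified.
  Under a depth-3 kernel with symmetric padding followed by depth max
  pooling, swapping the order is equivalent to permuting kernel weights, so
  the choice is immaterial to expressiveness; it is fixed for determinism.
* **SiLU on the input branch.** The activation is only stated for the
  suppressed (attention) branch. We treat both branches symmetrically and
  also activate the 3D-conv output before depth pooling; asymmetric
  variants can be recovered through `activation = "identity"`.
* **Baseline parity block.** The baseline stem outputs features at H/2, the
  BSI stem at H/4. To isolate the stem as the only difference, the baseline
  body inserts one extra stride-2 convolution before the head so both
  variants reach the same stride-16 grid, with otherwise identical body
  widths.
* **Reference backbone for the FLOPs audit.** At toy scale the fixed cost
  of the 3D convolution dominates and the BSI/baseline ratio is ~0.63, even
  though the absolute count is already lower. The compute claim ("under a
  third") belongs to the regime of full-size backbones at 640 px, so the
  audit uses `reference_backbone_specs()` — a conventional 4-stage conv
  backbone (widths 64/128/256/512) — where halving every downstream
  resolution yields a ratio of ~0.29. Both scales are reported;
  `detector_layer_specs()` gives the toy-scale inventory.

## The seen-to-unseen experiment

`run_experiment()` trains each requested variant on frames from one "seen"
environment and evaluates on held-out "seen" frames plus frames from an
"unseen" environment (new floor, relocated facilities). Per seed, the train
and seen-eval splits share one static background plate (as a fixed camera
would); the unseen environment has its own. Evaluation always uses the
*target* environment's own background model — the method's premise is that
preprocessing is a one-time, per-camera setup step, not something learned.

Run `scripts/acceptance.R` for the full numbers. In our study conditions
the ranking on the unseen environment is stable across seeds:

* **BIG + BSI ("big")** far exceeds the raw-frame baseline: the suppressed
  view is nearly environment-invariant (static content cancels), and the
  attention stage lets it gate the environment-sensitive raw view.
* **Adding FIG ("big_fig") collapses the unseen score** below the baseline.
  Diagnostics show its false positives concentrate on the *relocated,
  whitened* facility bars with high confidence. Mechanistically: background
  suppression already deletes static facilities from the suppressed view;
  whitening re-introduces them as bright blobs whose positions are
  environment-specific, so the invariance that made "big" generalize is
  destroyed. The facility-masking idea presumes occluders that survive in
  the network input (as in real, visually complex pens); in this simulator
  the suppressed view handles them better on its own.

This is an honest negative result for the full pipeline under our
generator, and it is reported as such rather than tuned away; see the
acceptance notes in the repository for details.

## Limitations

* The simulator's simplifications (static ellipses, exact plates, clean
  depth) favor background suppression more than real footage would; the
  FIG result above should be read in that light.
* The toy detector is single-scale and anchor-free with a handful of
  channels; it ranks preprocessing variants but its absolute AP50 values
  carry no meaning outside this package.
* AP is computed from a single confidence sweep over at most a few hundred
  detections; with 10 evaluation images it is quantized and seed-noisy,
  which is why medians over seeds are reported.
* Training is full-batch-sequential CPU arithmetic in base R; it is
  deterministic but slow beyond ~200x200 images or ~50 channels.
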