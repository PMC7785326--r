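---
title: "Loading codes: training cell-segmentation models from hyper-labeled stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loading codes: training cell-segmentation models from hyper-labeled stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(substacks)
```

## The problem

Deep segmentation models for microscopy are usually trained on images with a
fixed channel layout: a particular fluorescent marker, or a label-free
brightfield image. That makes labeling strategies hard to compare (each
strategy needs its own dataset) and makes the trained model brittle: a cell
that lost its cytoplasmic tag, or an experiment that dedicates the spectrum
to biosensors instead of segmentation markers, presents input the model has
never seen.

Microscope images have a property that side-steps both problems: channels
are co-registered, independent planes. From one *hyper-labeled* source stack
— here, three fluorescence markers (cytoplasm, membrane, mitochondrial
matrix) plus brightfield at seven focal offsets (−10, −5, −3, 0, +3, +5,
+10 µm) — any subset can be assembled into a new, representative
three-channel *subimage stack*. Assembly is described by a **loading code**:
per output channel, one of

* **simple** — load a named channel directly;
* **random** — load one channel drawn uniformly from a candidate set;
* **merge** — average several channels pixelwise into one.

Each output channel additionally carries a **channel dropout** rate (the
probability that the resolved channel is replaced by an all-zero blank,
emulating an unlabeled cell), and each merge member a **merge dropout** rate
(the probability that the member is blanked before averaging). Because
assembly happens per sample per epoch, dropout acts as an augmentation: one
dataset emulates the whole spectrum of labeling conditions.

## Merge semantics

The merged channel is the pixelwise arithmetic mean over *all* members;
a dropped member contributes zeros and the denominator stays at the member
count. Dropout therefore *dims* the merged channel rather than renormalising
it, and a merge dropout rate of 1 produces an all-black channel — the same
input as the label-free limit, which is what makes the 100% row of a
merge-dropout sweep behave like a label-free model. Whether a real
implementation should renormalise by the surviving count is genuinely open;
`renormalize = TRUE` on `resolve_channel()` / `assemble_subimage()` selects
the mean-over-survivors alternative. Dropout decisions are drawn in a
canonical member order so a merge is exactly invariant to how its members
are listed.

Single-channel models (cytoplasm, brightfield, ...) must still feed a
3-input network. The built-in codes replicate the one resolved channel
across all three inputs (`single_channel = "replicate"`); zero-padding the
unused inputs is available as `"pad_blank"`. Replication preserves the
3-channel encoder contract without inventing blank co-channels.

## The synthetic world

No external data ships with the package; every protocol is exercisable on a
simulator that reproduces the *structure* of a hyper-labeled single-cell
dataset:

* **Geometry.** Cells are ellipses perturbed by 2–6 smooth Fourier
  harmonics (one `boundary_roughness` knob). The centre cell always fits in
  the frame and spans roughly half of it, as in single-cell crops; with
  probability 1 − 0.26 at least one neighbour touches it (a hairline 0–2 px
  gap — membranes keep adjacent cells distinct). The ground-truth mask
  covers the centre cell only.
* **Cytoplasm** fills each cell to its contour with smoothly varying
  intensity; per-cell brightness varies (expression variability), and a
  shallow dark seam runs along every outline (membranes exclude cytoplasm),
  which is the cue that lets models separate touching cells.
* **Membrane** is a bright band of configurable width centred on each
  outline.
* **Mitochondria** are Gaussian speckles clustered towards a random
  perinuclear direction, confined at least `mito_margin` px (and a random
  15–60% of the cell radius) inside the boundary. The variable extent is
  deliberate: it makes the cell boundary genuinely unpredictable from the
  speckle hull, which is why mitochondrial markers segment worse than
  boundary-touching markers.
* **Brightfield** is mid-gray with faint per-cell brightness offsets and
  low-contrast texture in focus. Defocus adds a difference-of-Gaussians rim
  along each contour with signed amplitude `sign(offset) · rim_gain ·
  |offset|`: bright rims above focus, dark rims below, nothing at 0 µm.
  This reproduces the peaks-or-valleys boundary profiles of defocused
  transmitted light at negligible cost; it is *not* a physical
  point-spread-function model, and no claim about absolute brightfield
  accuracy should be read off it.
* A `negative_fraction` (default 175/450) of images are cell-free with
  all-background masks; markers can be independently absent per image.

Intensity distributions, SNR and cell-size statistics of real data are not
characterised by the source material, so these defaults are stated choices,
not calibrated values. A green directional test therefore establishes that
the *protocols* behave as described on data with this structure — not that
any particular accuracy number transfers to a real microscope.

## Network and training

The network is a U-Net with a ResNet34-topology descending arc (7×7 stem,
max-pool, stages of 3/4/6/3 basic blocks; total downsampling ×32) and a
custom ascending arc that upsamples by **pixel shuffle** — a pure index
rearrangement of `r² C` channels into `C` channels at `r×` resolution,
avoiding transposed-convolution checkerboard artifacts — with one
concatenation skip per resolution level. Because no deep-learning framework
exists in this environment, the layers, backpropagation and Adam are
implemented in the package (RcppArmadillo kernels for convolution, pooling
and batch normalisation); gradients are verified against finite differences
in the test suite. `width_multiplier` and `encoder_depth` scale the
topology for CPU-scale runs; defaults reproduce the full shape. Encoders
initialise randomly; a pretrained descending arc can be injected from a
checkpoint file (`load_checkpoint(..., encoder_only = TRUE)`) — no weight
download is part of the package.

The loss is the weighted cross-entropy
`loss(x, cls) = weight[cls] (−x[cls] + log Σⱼ exp x[j])` with defaults
cell = 1, background = 0.5; the lower background weight trades false
positives for false negatives, which most masking applications prefer.
Per-pixel losses are aggregated as their plain arithmetic mean, so the
single-pixel loss equals the printed formula exactly (a weighted mean —
dividing by the summed weights — was considered and rejected because it
changes the hand-checked single-pixel values).

Training runs in two phases: `frozen_epochs` (default 5) with the whole
descending arc frozen, peak learning rate 2×10⁻⁴, then `unfrozen_epochs`
(default 100) with discriminative group rates whose peaks span 2×10⁻⁶ to
1×10⁻⁴ geometrically across five parameter groups (stem+stage 1 lowest …
decoder+head highest). Each phase follows a 1-cycle schedule — cosine
warmup to an exact peak over 25% of iterations, cosine anneal to
peak/10⁴. The warmup fraction and divisors are this package's defaults;
the source material calls its schedule "a variation of the 1 cycle policy"
without specifying them. A learning-rate finder (`lr_find()`) ramps
geometrically from 10⁻⁷ to 10⁻¹ over 100 iterations and suggests the rate
at the steepest descent of the smoothed loss before divergence.

Validation applies only a centre square crop and resize. Loading-code
randomness stays active at validation so that, e.g., a random-brightfield
model is validated on what it will see in practice — but with seeds fixed
per (epoch, sample), so accuracies are comparable across models and runs;
the sweep protocol overrides the validation dropout rate explicitly.
The 80:20 split is seeded; within a replicate all compared models share the
split and the initialisation. This matters: repeated runs with a consistent
split reproduce accuracy exactly, while re-randomised splits spread it,
so relative performance is only meaningful under shared splits (the
reproducibility test demonstrates both).

## Augmentation

Geometric transforms (dihedral, rotation, skew, perspective warp, jitter —
implemented as translation; "jitter" is interpreted as spatial, not
intensity, jitter) compose into one homography applied with identical
parameters to image and mask, zero-filling out-of-frame regions to avoid
twin-cell artifacts. The warp samples **nearest-neighbour for image and
mask alike**; bilinear interpolation appears only in the final resize of
image channels. This deviates from the common bilinear-image convention
deliberately: it keeps image and mask perfectly synchronised (the test
suite feeds the mask through as an image and demands exact equality) and
keeps binary channels binary, at an invisible cost at 400 px scale. Masks
are re-thresholded at 0.5 after every resampling, so binarity is a
guarantee, not an accident. Photometric brightness/contrast applies to
image channels only. Default magnitudes are mild (±10% brightness, ±15%
contrast, rotation ±180°, shear ≤0.15, warp ≤0.2, jitter ≤5%) — the source
material states only that ranges "produced realistic cell images", so these
are configurable package choices.

## Evaluation protocols

`pixel_accuracy()` is the fraction of agreeing pixels; per-image accuracies
are averaged unweighted over the validation set (negatives included). The
headline number for a model is the mean validation accuracy over the final
10 epochs (`rolling_final_accuracy()`). `compare_strategies()` trains one
model per loading code per replicate under shared splits and
initialisation and reports mean ± s.e.m. with a two-sided paired t-test
against a reference code; zero-variance differences are flagged degenerate
rather than given a p-value. `dropout_sweep()` crosses the dropout rate
used in training with the rate imposed at validation into an accuracy grid;
the diagonal reproduces each model's standard validation accuracy by
construction, and row ranges quantify robustness. Sweep overrides apply to
every dropout-bearing spec of the template (merge dropout when the template
contains a merge, channel dropout otherwise).

## Numerical choices and degenerate inputs

* Argmax ties in mask prediction go to background, biasing against false
  positives.
* Stacks are stored as uncompressed 16-bit multi-page TIFF with channel
  names in per-page tags; a round trip is exact to 1/65535. TIFF I/O is
  implemented in the package because the environment offers no TIFF
  reader; an independent Python reader verifies the format in the tests.
* Missing channels are an error under the default strict policy; the
  blank-substitute policy must be opted into, preventing silent
  degradation to the all-black model.
* All randomness flows from explicit integer seeds through a single
  save/restore helper, so datasets, splits, assemblies, augmentations and
  training histories are bit-reproducible; derived seeds stay below 2³¹.
* Batch statistics are used during training and running statistics at
  inference; with one-pixel bottleneck feature maps (tiny inputs) batch
  variance can be near zero, which the ε = 10⁻⁵ floor absorbs.

## Scaled-down protocol tests

The full protocol (105 epochs, 400 px inputs, full-width encoder) is a
GPU-day of work; the package's tests reproduce the *directional* findings
at desk scale: a 1/8-width network, 60 synthetic images at 96 px, 12
epochs, and learning rates raised accordingly (3×10⁻⁴–5×10⁻³; the paper's
rates assume a pretrained full-width encoder). Under these conditions
cytoplasm and membrane codes outrank mitochondria and brightfield,
everything beats the all-black control, mid-rate merge-dropout training is
flattest across validation rates, and a 0%-trained model degrades when
fluorescence disappears. Absolute numbers at this scale are not
comparable to full-scale results and are not asserted.

## Known limitations

* The simulator's intensity statistics are invented; only structural
  properties are faithful.
* Defocus is a signed rim model, not optics; instance labels, 3-D stacks
  and physically accurate PSFs are out of scope.
* The decoder's exact channel counts and normalisation placement follow
  the common ResNet-U-Net pattern; the source schematic does not pin them
  down, and no bit-level fidelity to the original network is claimed.
* Weighted (non-uniform) merges and nested merges are unsupported.
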