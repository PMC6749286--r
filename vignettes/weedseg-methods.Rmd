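---
title: "Methods: mobile crop/weed segmentation, distillation and auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mobile crop/weed segmentation, distillation and auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedseg)
```

## The problem

Automated weeding machines need a per-pixel decision — soil, crop or
weed — fast enough to drive a tool from a moving tractor, on hardware in
the Raspberry-Pi class. Color thresholds fail when weeds and crops are
equally green, similarly sized or adjacent, so the decision has to come
from a convolutional segmentation network; the engineering problem is
fitting such a network into a tight multiply-accumulate (MAC) budget
without giving up accuracy, and training it without an enormous corpus
of hand-labelled field images.

`weedseg` implements a complete, desk-scale version of that pipeline:

1. a **stationary U-Net** teacher trained on hard (manual-style) labels;
2. an **ensemble** of independently trained teacher instances whose
   per-pixel class probabilities are averaged;
3. a **mobile hybrid** (U-Net skeleton, depthwise-separable
   convolutions, DenseNet-style blocks, residual tail) trained by
   **knowledge distillation** from the ensemble's soft output;
4. Dice-based **metrics**, a MAC-auditing **computation graph**, and a
   seeded **synthetic field generator** so everything runs end-to-end
   with no proprietary data.

## Models

Both models map an RGB image to class probabilities at 1/4 of the input
resolution — about 9 mm/pixel at the nominal camera geometry, coarse
enough to be cheap and fine enough to aim a weeding tool. A 320×240
frame yields an 80×60 probability map; the 320×112 on-device crop
yields 80×28.

**Stationary teacher.** A 4-level U-Net encoder of full 3×3
convolutions at widths `f_mobilenet(base, alpha)` for bases
(64, 128, 256, 512), 2×2 average pooling between levels, a bottleneck
at 1/16 resolution, and a two-level decoder (nearest-neighbour upscale,
skip concatenation, 3×3 convolution) that stops at 1/4 resolution; a
pointwise projection and a per-pixel softmax finish the model. Inputs
must be divisible by 16. Training sweeps here use `alpha = 0.3`: single
instances are cheap to train and the accuracy gap closes in the
ensemble anyway.

**Width schedules.** The MobileNets-style schedule is
`f_mobilenet(x, alpha) = max(1, floor(x * alpha))`. On low-cost ARM
boards, inference kernels are dramatically faster when channel counts
are sums of few powers of two — shrinking 64 channels to 62 can be
*slower* — so the mobile model uses the quantized schedule
`f_mod8(x, alpha) = max(8, 8 * floor(x * alpha / 8))`, which keeps the
MAC-versus-alpha curve a monotone step function. The mobile stage
widths are the triple `(A, B, C) = (f(16), f(32), f(64))`. A small
epsilon is added before flooring so exact rational boundaries
(`40 * 0.15 = 6`) are not lost to binary floating point.

**DenseNet-Mobile blocks.** A dense block concatenates its input with
every stage's output; each stage contributes `growth` channels. The
separable ("mobile") adaptation makes each stage a depthwise 3×3
convolution followed by a pointwise convolution (+ batch norm + ReLU).
Two wirings are provided:

* *naive*: each stage re-filters its whole concatenated input, so a
  channel entering at stage 1 of an `L`-stage block is depthwise
  filtered up to `L` times; a resolution-reducing block runs all stages
  at the input resolution and average-pools the concatenated output;
* *custom*: every channel is depthwise-filtered **exactly once**, when
  it first appears, and later stages read the cached filtered maps; a
  reducing block pools its input *first*, so all computation runs at
  the reduced resolution.

The two wirings emit identical channel counts, and with depthwise
kernels tied across stages ([tie_depthwise_weights()]) the non-reducing
forms are numerically identical — that equivalence, checked to 1e-5
over random inputs, is the correctness oracle for the custom wiring.
The reducing forms are *not* equivalent by construction (pool-early is
an approximation adopted for speed), which is why the equivalence claim
and test cover only non-reducing blocks. On the MAC audit the custom
wiring is never more expensive and strictly cheaper whenever `L >= 2`
or the block reduces.

The reducing-naive wiring deserves a note: the naive form is defined
here as reducing *late* (stages at input resolution, pooled output).
Reducing in the first stage instead would make a one-stage reducing
block cost exactly as much as the custom form — early reduction is
precisely the custom block's advantage, so the reference wiring must
not already have it.

**Mobile hybrid.** Stem: full 3×3 stride-2 convolution to width A;
encoder: reducing block → pointwise transition to B, reducing block →
transition to C, non-reducing block at C (block growth is half the
block's input width); decoder: nearest-neighbour 2× upscale (cheap
replacement for a transposed convolution), skip concatenation from the
width-B stage, pointwise fusion to B, `n_residual = 2` separable
residual units, pointwise head, softmax. Inputs must be divisible
by 8. Exact stage-width assignment inside the hybrid is a design
choice of this package; it satisfies every structural constraint the
architecture is defined by (total factor 4, (A,B,C) widths, scaling
instead of transposed convolutions, final residual units).

## Training

* **Loss.** Mean per-pixel cross-entropy. Hard labels use the codes
  0/1/2 with 255 = ignore; ignored pixels contribute no gradient.
  Distillation uses soft-target cross-entropy at temperature 1 against
  the teacher's full distribution (equal to KL divergence up to the
  constant teacher entropy); every pixel participates, which is what
  lets distillation consume unlabeled imagery.
* **Optimizer.** Adam, learning rate 1e-3, default batch 4. The
  execution engine is written in-package (shift-and-add convolutions on
  BLAS-backed matrices with exact analytic gradients, verified against
  finite differences to 1e-7); no deep-learning framework is used.
* **Batch norm** follows every convolution (a flag disables it);
  training uses batch statistics and momentum-0.1 running statistics
  for inference.
* **Border exclusion.** Hand labels are least reliable at class
  borders, so pixels within Chebyshev radius 1 (output grid) of a
  different class are ignored during stationary training. At the
  desk-scale 12×12 output grid this radius would swallow entire 1–2 px
  weed blobs — an artifact of the coarse grid, not of the idea — so
  the bundled studies train with radius 0; the package default
  stays 1.
* **Augmentation.** Brightness and saturation scales drawn from
  [0.7, 1.3] (image only) and independent horizontal/vertical flips
  with probability 1/2 (image and label jointly); values clipped to
  [0, 1]. The ±30% range is a package default.
* **Label resolution.** Full-resolution masks are majority-vote
  downsampled 4× (ties → ignore), keeping the generator output
  independent of any particular model stride.

## Ensembling and distillation

Independently initialized and trained stationary instances make
mostly-correct but noisy predictions; averaging their per-pixel
probabilities suppresses the noise. The per-class marginal median is
available as an alternative combiner (renormalized per pixel, since
marginal medians need not sum to one); historically it was slightly
worse than the mean and the mean is the default. Ensemble size is
chosen by a stability argument — when the first and second half of the
ensemble segment held-out images nearly identically, the ensemble is
big enough — implemented as [ensemble_stability()]. The reference
ensemble size is 50; the bundled desk-scale studies use 5.

The ensemble is expensive, so it never ships: it acts as a *teacher*,
labelling arbitrary amounts of unlabeled imagery with soft
distributions from which the mobile *student* is trained.

## Synthetic fields

The generator emulates the geometry the models were designed for: a
brown soil background with low-frequency value noise, one crop row
running down the image center (rosettes of 5–9 overlapping green
ellipses), Poisson-scattered smaller irregular weed blobs whose hue is
shifted 15° toward yellow-green, optional harsh diagonal lighting with
a hard shadow, and later-drawn plants occluding earlier ones. Ground
truth is exact by construction and never contains ignore pixels.

What it does *not* emulate: species-specific morphology, leaf texture,
soil clutter (stones, straw), motion blur, perspective, or the
continuous appearance drift of real video. Passing tests on this data
therefore demonstrates that the pipeline's mechanics are correct and
that its qualitative effects (ensembling helps; distillation beats
equally sized direct training) are reproducible — not that field-scale
accuracy numbers transfer.

Desk-scale study conditions (fixed, seeded): 48×48 frames treated as
*crops* of the nominal scene, so plants keep near field scale (crop
radius 9–14 px, weed radius 4–8 px — weeds span 1–2 output pixels,
exactly the resolution budget of the full geometry); 12 training and 6
held-out fields; 5 ensemble members at reduced encoder widths
(16, 32, 48, 64) and `alpha = 0.3`, 120 epochs each (chosen from loss
convergence); students at `alpha = 0.5`, mod8 schedule, custom blocks,
240 epochs, with the distilled and the directly trained student seeing
the *same* 12 fresh images — soft teacher labels versus ground-truth
hard labels.

## Metrics

For label region E and prediction region P of a class,
Dice = 2|E∩P| / (|E| + |P|). The segmentation error `e_dice` is 100%
minus the mean Dice over images and the three classes; weed recall,
weed precision and crop-as-weed are pooled pixel ratios over the whole
evaluation set (their per-image breakdown is available behind a flag).
Conventions this package fixes explicitly: ignored label pixels are
excluded from **every** count; a class absent from both label and
prediction contributes Dice 1 by default (`absent = "skip"` drops such
pairs instead); an empty ratio denominator yields `NA` with a warning,
deliberately distinct from 0. All four metrics are verified against an
independent brute-force pixel-counting oracle on random mask pairs.

## Numerical choices and degenerate inputs

* Same padding everywhere; downsampling only via stride 2 or 2×2
  pooling, so shape propagation is exact and inputs must divide the
  total factor (errors name the offending node).
* Argmax ties break toward the lowest class index (soil < crop <
  weed).
* Softmax is computed with the row-max subtracted; cross-entropy clamps
  probabilities at 1e-12.
* He (fan-in) initialization, zero biases, unit-gain batch norm;
  weight init, shuffling, augmentation and field generation all derive
  from explicit integer seeds, so every run in this package is exactly
  reproducible.
* MAC accounting: output positions × kernel² × in × out for full
  convolutions, × kernel² × channels for depthwise, × in × out for
  pointwise; pooling, scaling, concatenation, addition, normalization
  and activations count zero.

## Known limitations

* The engine is single-threaded R; it is meant for desk-scale
  experiments and audits, not for field-scale training runs.
* Wall-clock benchmarking is reported but never asserted — MACs are
  the portable cost measure; real-device effects (the power-of-two
  kernel cliff that motivates `f_mod8`) are represented structurally,
  not timed.
* Reported field-scale accuracy figures from the original system are
  not reproducible on synthetic desk data; the package asserts
  directions of effects, never those magnitudes.
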