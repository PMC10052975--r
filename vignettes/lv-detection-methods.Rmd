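---
title: "Detecting the left ventricle in relaxometry stacks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the left ventricle in relaxometry stacks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ViTLV)
```

`ViTLV` localizes the left ventricle (LV) in short-axis multi-echo cardiac
MR relaxometry stacks by regressing a normalized bounding box with a Vision
Transformer. This vignette is the package's account of its own methods: the
signal and geometry model behind the synthetic phantoms, the ground-truth
conventions, the detector architecture and its training protocol, the
numerical choices made where the design was genuinely open, and the limits
of what the synthetic experiments demonstrate.

## The detection problem

A T2\* relaxometry study acquires each short-axis slice at a train of echo
times; tissue signal decays mono-exponentially with the echo time at a
tissue-specific rate. Unlike cine imaging — where the heart is the only
thing moving on an almost static background — *every* tissue in a
relaxometry sequence changes appearance across frames, so the detector must
recognise the LV by shape and joint multi-frame appearance rather than by
motion. The LV is an annulus of myocardium around a bright blood pool,
located off-centre in a 256 × 256 field of view that contains chest wall,
lungs, liver and other bright, similarly shaped structures.

The detector consumes three frames of the echo train (the first, fifth and
ninth echoes by default, i.e. TE = 2.0, 11.04 and 20.08 ms of a 10-echo
train starting at 2.0 ms with 2.26 ms spacing) and emits the normalized
top-left and bottom-right corners `(x1, y1, x2, y2)` of the tight box
around the epicardial contour. Coordinates follow image conventions
throughout: origin at the top-left pixel, x along columns, y along rows and
increasing downward.

## The synthetic phantom generator

Clinical relaxometry studies with manual contours are not redistributable,
so the package ships a generator whose samples carry exact ground truth.
Every pixel belongs to one tissue and decays as

$$S(TE) = S_0 \, e^{-TE/T},$$

multiplied by a linear coil-sensitivity gain and summed with additive
zero-mean Gaussian noise. The defaults are the generator's experimental
conditions, chosen once:

* **Geometry.** 256 × 256 pixels (reduced-resolution phantoms scale the
  anatomy linearly); the LV is a pair of concentric rasterized ellipses with
  random rotation and eccentricity ≤ 0.5. Epicardial semi-axes are drawn
  per slice type — basal 30–44 px, middle 24–38 px, apical 16–28 px at 256 px
  resolution — so apical slices are genuinely smaller, as they are
  anatomically. The LV centre is drawn uniformly within ±25 px of the image
  centre (within a subject, slices share a centre up to ±2 px).
* **Timing.** Ten echoes, TE₁ = 2.0 ms, spacing 2.26 ms.
* **Tissue parameters.** The myocardial decay constant is drawn per subject
  uniformly in 2–57 ms, the clinically observed span of global T2\* from
  severe iron overload to normal; blood (80 ms), liver (20 ms), chest wall
  (25 ms), lung (5 ms) and background values are plausible 1.5 T
  bright-blood defaults, not literature fits, and are documented as such in
  `?phantomSpec`.
* **Confounders.** One to three bright elliptical blobs with blood-like
  signal are placed outside the LV to emulate isointense structures.
* **Shading and noise.** A multiplicative linear gradient of fractional
  slope 0.15 in a random direction models coil sensitivity; additive
  Gaussian noise (σ = 2 arbitrary units against a myocardial S₀ of 100)
  models thermal noise. Magnitude-MR Rician noise is deliberately out of
  scope: at the blood/myocardium signal levels that drive detection the
  Gaussian approximation is adequate, and it keeps every decay-law test
  closed-form.

Phantoms are bit-for-bit reproducible from `(spec, seed)`. What the
generator does **not** emulate: pulse-sequence physics (inversion-recovery
schemes, black-blood preparation), k-space artefacts, respiratory or
cardiac motion, slice misalignment, and real anatomical texture. Passing
the scaled-down learning experiment therefore shows that the architecture,
gradients, loss and protocol work as specified — not that the trained
weights transfer to clinical images.

## Ground truth and segmental analysis

* **Bounding box.** The least rectangle containing every epicardial pixel,
  with half-open pixel extents: a pixel at 0-based `(r, c)` occupies
  `[r, r+1) × [c, c+1)`, so `x1 = min_col / C` and `x2 = (max_col + 1) / C`.
  This makes the box contain each pixel's full extent and makes
  `bboxFromMask()` idempotent under cropping and monotone under mask
  inclusion.
* **Blood-pool centre.** Read as the midpoint of the tight box around the
  endocardial mask (not the mask centroid); `bpCentre(centre = "centroid")`
  provides the alternative. For the symmetric shapes involved the two
  nearly coincide.
* **Segments.** The myocardium (epicardial minus endocardial mask — the
  boundary-pixel convention is asserted, pixels on both contours belong to
  the blood pool) is divided into equiangular sectors around the blood-pool
  centre: six in basal and middle slices, four in apical ones. The angular
  origin of the standard segmental model is software-specific, so
  `referenceAngle` is configurable; the default places sector 1 at the
  anterior (upward) direction with clockwise numbering.
* **T2\* fitting.** Per segment, the mean signal across echoes is fitted
  with `S₀ e^{-TE/T}` by Levenberg–Marquardt nonlinear least squares
  (`minpack.lm`), initialized from a log-linear regression weighted by
  `S²` — the weights under which log-domain least squares matches the
  linear-domain objective to first order. The fit is exact on noiseless
  exponentials; non-decaying input returns a flagged (`converged = FALSE`),
  possibly infinite estimate rather than an error, since a segment of pure
  noise is a data condition, not a bug. The global value is the arithmetic
  mean of exactly the 16 segmental values (6 + 6 + 4); any other count is
  rejected.

## The detector

`vitConfig()` encodes the reference architecture for 256 × 256 × 3 input:
patch size P = 32 (N = 64 patches of flattened width P²·Nf = 3072),
embedding width D = 64, h = 4 attention heads with dropout 0.1, a 128/64
GELU MLP (dropout 0.1) in each encoder block, and a 2048/1024/512/64/32
GELU regression head (dropout 0.3) ending in a linear 4-unit layer. Blocks
are pre-norm: `U = X + MHSA(LN(X))`, `X' = U + MLP(LN(U))`, with a final
layer normalisation before the head.

Design points that were genuinely open, and how they were settled:

* **Encoder depth.** Not part of the published hyper-parameter set; the
  default is 4 blocks, matching the public Keras object-detection ViT this
  architecture follows, and is exposed in the configuration. This is the
  largest architectural unknown.
* **Attention scaling.** Two scalings of the attention logits circulate:
  the per-head form `softmax(QKᵀ/√(D_q/h))V` and the generic definition's
  `√D_q`; most implementations divide by the per-head width `√(D/h)`.
  Both are implemented: `scaleConvention = "paper"` (default) honours the
  per-head form as printed, dividing by `√(d_head/h)`;
  `"per_head"` uses the conventional `√d_head`. The standalone
  `selfAttention()` operation always uses `√D_q` of its own weight
  matrices. The difference is a temperature factor and does not change
  the normalisation or equivariance properties.
* **No class token; flatten, not pool.** The N × D encoder output is
  flattened into a single vector for the regression head. Parameter counts
  (pinned in the tests: 11,383,460 for the reference configuration) are
  only comparable to other implementations under the same reading.
* **Positional encoding.** A learned per-index table by default;
  fixed sinusoidal encodings are available. With the table zeroed the
  encoder is exactly permutation-equivariant in the patches, which the
  tests exploit.
* **Output head.** Linear activation during training — the loss handles
  the geometry; at inference the four raw outputs are clipped to [0, 1]
  and corner-sorted, and a degenerate axis is widened by 10⁻⁶ so the
  returned box is always valid.
* **Initialization.** Truncated normal (σ = 0.02, ±2σ) for weights, zeros
  for biases, unit layer-norm gains, layer-norm ε = 10⁻⁶ — standard ViT
  practice. The final regression bias starts at the central box
  `(0.25, 0.25, 0.75, 0.75)`: the 1−DICE loss has zero gradient whenever
  the predicted and true boxes are disjoint, so a head starting at the
  origin would never receive a learning signal. Central-box initialization
  guarantees initial overlap with any plausible LV position.

## Training protocol

The loss is `1 − 2|I|/(|pred| + |gt| + ε)` with ε = 10⁻⁷, intersection
and extents clamped at zero; it lies in [0, 1], equals `1 − 2J/(1+J)` for
IoU `J`, and is differentiable almost everywhere (the clamps contribute
subgradients at measure-zero kinks). Optimization is Adam (β₁ = 0.9,
β₂ = 0.999, ε = 10⁻⁷) with the exponentially decayed step size
`lr(t) = lr₀ · 0.96^(t/100000)` from lr₀ = 10⁻⁴, batch size 32, up to 300
epochs. There is no early stopping; the checkpoint with the lowest
validation loss is retained. Augmentation draws integer shifts uniformly
from ±20 px per axis, zero-fills vacated pixels, shifts the box by the
same normalized offsets and redraws the rare case where the box would
leave the frame entirely.

Splits are subject-grouped: the three slices of a subject always share a
partition, which is the property that prevents leakage. "Stratified" is
read as balancing fold sizes only — every subject contributes exactly one
basal/middle/apical triple, so slice composition is balanced by
construction. The five test partitions are disjoint and cover the cohort;
the validation set takes `ceiling(0.1 × remaining)` subjects of the
post-test remainder — the only rounding convention that reproduces the
documented 381/43/106-subject (1143/129/318-image) bookkeeping for 530
subjects, which is why the 10% is read against the remainder rather than
the full cohort.

All randomness in a training run (shuffling, augmentation, dropout)
derives from the training seed through a private RNG stream, so a run is
exactly reproducible and never disturbs the caller's RNG state.

## Metrics

IoU and DICE are continuous box areas (no rasterization), related by
`DICE = 2·IoU/(1 + IoU)`; the tests verify both against an independent
rasterized-area oracle. ε_CP,A is the Euclidean distance between box
centres in pixels; the fractional errors divide it by `√(area/π)` of the
epicardial and endocardial masks. A CIR hit maps the continuous box centre
to the pixel containing it (floor) and looks it up in the endocardial
mask — boundary pixels count, a centre off the image is a miss. The
per-slice summary reports mean ± SD per slice position; the Global row
pools all records rather than averaging the slice rows (the natural
summary of a single test set; with balanced slice counts the two differ
little).

ε_CP,A is reported in pixels. On a 256-pixel, 35 cm field of view one
pixel is ≈ 1.37 mm; `writeImageStack(pixdim = )` can carry the spacing for
mm conversion downstream.

## Scaled-down experiments and problem sizes

The package's own experiments (test suite and `scripts/acceptance.R`) run
on reduced geometry chosen to keep the full loop — simulate, train,
predict, evaluate — in tens of seconds on one CPU: 100 subjects × 3 slices
at 64 × 64 px, the `reducedViTConfig()` architecture (P = 16, D = 32,
h = 4, 2 blocks, 64/32 encoder MLP, 512/128/32 head; 374,852 parameters),
one subject-grouped fold, 30 epochs, batch 32, shift range ±5 px (the
±20 px of the full protocol scaled by the 64/256 resolution ratio). For
this short-schedule small model the Adam step size is 10⁻³ — the canonical
Adam default for training small networks from scratch in a few hundred
steps; the 10⁻⁴ of the full protocol is tied to its 300-epoch budget. The
convergence smoke test additionally disables dropout and runs full-batch,
where descent on the training loss is deterministic and monotone.

## Known limitations

* The phantoms' simplified anatomy means synthetic performance numbers say
  nothing quantitative about clinical data; they validate the machinery,
  not the weights.
* Training is CPU-bound base R; the reference 11.4 M-parameter
  configuration trains at desk scale only for smoke purposes, though its
  forward pass is fast (tens of milliseconds per image).
* The 1−DICE loss is blind outside box overlap; detection quality at
  initialization rests entirely on the central-box bias.
* Statistical hypothesis testing across slices or acquisitions is out of
  scope; the per-image records CSV is designed to be consumed by any
  statistics package.
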