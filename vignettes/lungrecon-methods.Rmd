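---
title: "Methods: reinforcement-regularized adversarial lung-tumor analysis at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reinforcement-regularized adversarial lung-tumor analysis at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`lungrecon` implements a three-stage thoracic-CT analysis pipeline — lung
segmentation, tumor detection, and 3-D tumor reconstruction — together with
a synthetic thorax-phantom generator that makes every stage trainable and
testable on one CPU in minutes. The pipeline follows a specific family of
methods: a U-Net-style per-pixel classifier trained as a reinforcement
learning policy with an off-policy proximal policy optimization (PPO)
surrogate plus a Wasserstein-style adversarial critic; a lite
Mask-R-CNN-style detector with classification, box-regression and
adversarial losses; and a spatial-attention transductive LSTM (TLSTM)
feeding a deconvolutional 3-D generator trained with mean absolute error
(MAE) plus a weighted adversarial term.

No deep-learning framework is used: the package carries its own small layer
library (2-D/3-D same-padded convolutions with optional dilation via
compiled `im2col`, pooling/upsampling, dense layers, instance
normalization, peephole LSTM) with hand-derived backward passes. Every
backward pass is pinned by finite-difference tests, and the LSTM cell is
additionally checked against an independently written scalar oracle at
hidden sizes 1–3 to 1e-10. This keeps the package self-contained and every
gradient auditable.

# The phantom generator

The phantom emulates the statistical structure of annotated thoracic CT
without reproducing anatomy. Lung fields are two mirrored ellipses per
slice whose in-plane semi-axes solve $2\pi a b = f S^2$ for a target lung
fraction $f$ (aspect ratio $b/a = 1.9$ fixed), modulated along $z$ so that
the stack is a smooth, contiguous 3-D body; the modulation is normalized so
the mean slice area matches the target, which is how the generator keeps
the measured lung-pixel fraction within ±0.05 of `lung_fraction_target`.
Tumors are spheres, anisotropy-normalized ellipsoids, or lobulated blobs
(a sphere whose directional radius is perturbed by a low-order angular
harmonic), rasterized into the voxel grid and clipped to the lungs so the
containment invariant (tumor ⊆ lung) holds by construction. Intensities
are arbitrary units — background 0, lung −1, tumor −1 + `tumor_contrast` —
plus Gaussian noise; z-scoring happens in the pipeline, so no Hounsfield
calibration is implied.

What the phantom does **not** model: vasculature and airways, scanner
artifacts, lobe boundaries, pleural contact, and the intensity texture of
real parenchyma. Tests passing on phantoms therefore demonstrate that the
algorithms do what their equations say under controlled class imbalance and
slice-coherent geometry — not that the trained weights transfer to clinical
CT.

Two phantom regimes recur in the tests and the acceptance script, chosen
once as the study conditions:

* *imbalanced segmentation phantoms*: 64×64, 8 slices per case, lung
  fraction 0.12 (the minority regime the reward design targets), noise SD
  0.3 so one-to-two-epoch training stays away from both chance and ceiling;
* *sphere-tumor reconstruction phantoms*: 16×16×16 cases with spherical
  tumors of radius 2–2.5 voxels, from which tumor-centered crop sequences
  are built (stage 3 consumes detected tumor regions, not whole slices).

The 70/15/15 split is by case, not by slice, to avoid leakage between
splits; validation and test each receive `floor(0.15 n)` cases (at least
one), and the remainder trains.

# Stage 1: segmentation as a per-pixel policy

The generator is an encoder–decoder with skip connections producing a
per-pixel lung probability and, from the same feature map, a linear value
head $V(s)$. Each pixel is a one-step episode (a contextual bandit): the
action is the predicted label, the reward is asymmetric — a minority-class
(lung) pixel earns ±1, a majority-class pixel ±λ with λ = 0.5 by default —
and the advantage is $A = r - V(s)$. The discount γ = 0.68 is kept in the
configuration and used by the discounted-return helper only; it has no role
in a one-step episode.

A note on the reward's class condition: the asymmetry must be keyed to the
**pixel's true class**. Keying it to the predicted class instead gives both
classes the identical expected gradient weight $p + (1-p)\lambda$ and no
imbalance correction at all (we verified this empirically: the
predicted-class variant trains to the same minority recall as plain
cross-entropy). The package therefore scales the reward by the pixel's
class, which is also the reading under which "higher penalties for
misclassifying lung pixels" is true.

Training is genuinely off-policy. A behavior snapshot of the generator is
refreshed every `snapshot_every` updates, smoothed to
$\mu = (1-2\varepsilon)p_{snap} + \varepsilon$ (ε = 0.05) so that both
actions always retain behavior probability. The surrogate is the off-policy
clipped objective with clip bounds corrected by $\pi_{old}/\mu$. Because a
pixel has only two actions, the training loop evaluates the surrogate's
expectation over $a \sim \mu$ in closed form instead of drawing one action
per pixel: the estimator is exact, and the rare minority-pixel updates are
no longer starved by sampling variance (with one-sample Monte Carlo the
policy could collapse into the all-background solution on unlucky
initializations, a failure the cross-entropy twin does not share). Two
further standard PPO ingredients are kept: an entropy bonus
(`entropy_weight`, default 0.1) that counteracts saturation — at a
saturated pixel the value baseline exactly cancels the recovery signal, so
some pressure away from determinism is required — and the value head, which
regresses to the expected reward under μ. Per-image transition batches
(pixel indices, μ probabilities, labels) enter a bounded FIFO replay buffer
and are replayed every `replay_every` updates under their original μ. Pixel
subsampling (`pixels_per_image`, default 512) bounds the batch; pixels are
sampled uniformly so the batch keeps the natural class imbalance — the
reward, not the sampling, is the imbalance correction.

The critic is a dilated-convolution network scoring the pixel-wise fusion
mask ∘ image (both the real and the generated mask are fused with the CT
slice, making the two terms of the score-difference loss comparable), plus
a second input plane that emphasizes nodule areas (image ∘ tumor mask,
zeros without annotations). The loss is a Wasserstein-style score
difference; we stabilize it with weight clipping (bound
`critic_clip = 0.05`) rather than a gradient penalty, because a penalty
term requires second-order backpropagation that the hand-rolled layer
framework deliberately does not implement. The generator's composite loss
is (negated) PPO surrogate + `adv_weight` × (negative critic score on the
fused fake), with the value head trained by squared error to the reward.
Optimizer: SGD, momentum 0.85, weight decay 0.001; learning rates 0.002
(generator) and 0.001 (critic); batch-size 68, γ = 0.68 and the masking
threshold's midpoint 0.5 are carried as the tuned defaults of the method.

The cross-entropy twin (`objective = "ce"`) differs from the full method
only in the loss: same architecture, same seed, same sampled pixels, plain
unweighted cross-entropy, no critic. On the imbalanced phantom regime the
full method reaches higher minority-class recall than the twin after the
same two-epoch budget — the package's scaled-down analog of the ablation
direction reported for the original method.

# Stage 2: detection

A small convolutional backbone (leaky-ReLU; two 2× poolings, stride 4)
feeds 1×1 objectness and box-delta heads over a grid of anchors (single
scale/ratio by default; lists accepted). Anchor labeling follows the usual
RPN rules (IoU ≥ 0.5 or best-per-ground-truth positive; negatives below
0.1), with two desk-scale accommodations: anchors whose centers fall in or
near a tumor box are excluded from the negative pool (their receptive
fields overlap the positives', and conflicting labels on near-identical
features destabilize a head this small), and the sampled RoI batch uses
class-balanced cross-entropy with positives capped at `roi_positive_ratio`
(0.35). Box deltas are normalized by the refinement std (0.012); the head
predicts normalized deltas and decoding multiplies back. Learning rates
(0.01 generator / 0.001 discriminator) follow the method's tuned values and
decay by an inverse-time schedule, which stops the box head from
oscillating late in training. The RoI-level discriminator sees fixed-size
nearest-neighbor feature crops of predicted versus ground-truth boxes from
the shared backbone; its log loss and the generator's −log D term follow
the standard adversarial forms, with scores floored before logs and the
discriminator-to-feature gradient clamped (an unbounded −1/score gradient
early in training was observed to kill the backbone's units). The total
generator loss is the unit-weight sum of classification, box and
adversarial terms. A mask head (dense over RoI feature crops) produces the
per-detection mask crop, thresholded at `mask_threshold`.

# Stage 3: reconstruction

Each slice of a tumor crop sequence passes through a small frozen
convolutional encoder; spatial attention scores the resulting token matrix
(softmax over tokens, so the weights sum to one) and pools it to one
feature vector per slice; a stacked peephole LSTM (diagonal cell-to-gate
weights, as the cell is defined) folds the sequence; the final hidden state
concatenated with the mean hidden state maps through a dense head to a
$(S/4)^3$ seed tensor; and six generator blocks (3-D convolution +
instance normalization + ReLU, with nearest-neighbor 2× upsampling in
blocks two and four, sigmoid output) produce the occupancy grid. The
reshaping of the hidden sequence into the seed tensor is a design choice of
this package; the source method does not specify one. Instance
normalization stands in for batch normalization because training is
per-sequence (batch size one). The discriminator applies dilated 3-D
convolutions and a sigmoid head. The generator+TLSTM+attention parameters
minimize MAE + ∂·(−log D) with ∂ = 0.56 under Adam with betas (0.6, 0.65),
learning rates 0.001/0.0015; dropout 0.3 applies between stacked TLSTM
layers only. A 1-D earth-mover's distance between the occupancy histograms
of real and generated volumes is logged per epoch as a diagnostic; it does
not enter any gradient.

Transductive adaptation implements the TLSTM convention: pooled encoder
features define a Gaussian proximity kernel (bandwidth σ_k) over training
cases, and the trainable parameters take K full-batch gradient steps on the
proximity-weighted MAE before predicting the test sequence. K = 0 is a
bit-exact no-op; σ_k → ∞ equals uniformly weighted fine-tuning; adaptation
minimizes the MAE term only (the adversarial term is a training-time
regularizer, not a per-test-point objective). Whether adaptation should
touch all parameters or a subset is not specified by the source method; we
adapt all trainable groups (attention, TLSTM, head, generator) and leave
the frozen encoder out, since it defines the proximity space itself.

# Evaluation metrics

IoU, directed/symmetric Hausdorff distance, and a surface-based "ED" are
computed exactly as defined on voxel coordinates (optionally scaled by
spacing). Because corresponding point pairs are undefined for free-form
voxel reconstructions, the volume ED is interpreted as the mean symmetric
nearest-neighbor surface distance; HD uses the same surface point sets
(six-connected boundary voxels, grid border counted as background). Both
agree with brute-force double-loop oracles in the tests. The 1-D EMD is the
Wasserstein-1 cost via the CDF identity and is tested against an
independent sorted-atom transport oracle. Conventions for degenerate
inputs: IoU of two empty masks is 1 with a warning (perfect agreement of
empties), one empty mask gives 0; empty surfaces make HD/ED report `Inf`
sentinels with a warning rather than fail.

# Error propagation

`error_propagation()` mirrors the two-column-plus-difference structure of
the original study's analysis: detection metrics (top-box IoU against
ground truth; HD between box outlines) are computed once with ground-truth
lung masks and once with the segmenter's predictions as the stage input,
and reconstruction metrics (HD, ED) once from ground-truth tumor boxes and
once from predicted detections as the crop source. "Difference" is the
absolute difference of the two means; with `use_gt_predictions = TRUE` the
predicted arm is fed ground truth too, and every difference is exactly
zero — the harness's self-check.

# Determinism and problem sizes

All randomness flows from one integer seed through `derive_seeds()`; every
training loop, the generator, augmentation, buffer sampling and the
pipeline are bit-reproducible under a fixed seed on CPU. The problem sizes
used by the tests and the acceptance script — 200 segmentation images at
64×64 over 2 epochs, 14 detection cases over 16 epochs, 16 reconstruction
cases at 16³ over 8 epochs, networks of 4–8 channels and TLSTM widths 8–16
— are the package's chosen desk-scale study conditions: large enough for
the documented effects (imbalance benefit, detection hit rate ≥ 0.7,
trained-beats-untrained reconstruction) to be stable across seeds, small
enough to run interactively. The tuned defaults of the original method
(TLSTM 247 units × 4 layers, batch sizes 68/82/102, anchor scale 102 for
512-pixel CT) remain the documented defaults of the configuration objects.

# Known limitations

* Phantoms are geometric, not anatomical; none of the trained weights are
  meaningful for real CT.
* The critic's gradient-penalty-free stabilization (weight clipping) bounds
  its Lipschitz constant crudely; with large `adv_weight` the segmentation
  adversary can still dominate the PPO term.
* The detector uses a single feature level and nearest-neighbor RoI
  cropping; box gradients do not flow through box coordinates (crops are
  piecewise constant in the box), so the adversarial signal shapes the
  shared features only.
* Mesh export writes voxel-face surfaces (watertight but blocky), not
  smoothed marching-cubes isosurfaces.
* The per-pixel episode is one-step by construction; γ is inert outside the
  return helper, and multi-step credit assignment is out of scope.
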