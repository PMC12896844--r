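---
title: "Methods: carcass part segmentation and image-based weight estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carcass part segmentation and image-based weight estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Weighing broiler carcasses on a processing line is slow, contact-based and
error-prone. A vision alternative images each suspended carcass from three
standardized perspectives (ventral, dorsal, lateral), segments the carcass
and its parts (torso, head, legs) out of the dark background, converts the
per-part pixel counts to physical areas with an in-image calibration, and
regresses part weights on the multi-view areas. `ccwpipe` implements this
two-stage pipeline end to end on CPU, together with a procedural synthetic
carcass generator that makes every stage testable against closed-form
ground truth.

## Stage one: the segmentation network

The segmentation model is an encoder–decoder U-Net whose convolutional
units are **recurrent-residual blocks**: each block stacks two recurrent
convolutional layers and adds a shortcut (a 1×1 convolution when the
channel count changes). A recurrent layer refines its feed-forward
response `a = BN(conv_ff(x))` for `t` steps,

```
y_0 = relu(a),      y_s = relu(a + BN(conv_rec(y_{s-1}))),  s = 1..t,
```

so the effective depth grows without new parameters per step. `t = 2` by
default, following the recurrent-residual U-Net design this architecture
derives from; `t = 0` degenerates to a plain double convolution, which the
test suite exploits as an oracle case.

Two attention mechanisms are added:

* **Channel + spatial attention (CBAM)** on every skip connection. The
  channel gate pools each channel by mean and by max, passes both
  descriptors through a *shared* two-layer perceptron
  (`W1 relu(W0 v)`, reduction ratio `r`, default 16 capped at the channel
  count), sums, and squashes through a sigmoid. The spatial gate
  concatenates the channel-wise mean and max maps and convolves them with
  a single 7×7 kernel before the sigmoid. The inner ReLU of the shared
  perceptron follows the original CBAM design; the gate formula itself
  only prescribes the two linear maps. Because both gates live in (0, 1),
  CBAM can never increase an activation's magnitude — a property asserted
  over random tensors in the tests.
* **Selective-kernel (SK) attention** after every encoder block. Two
  parallel branches with 3×3 and 5×5 kernels are summed (`U = U1 + U2`),
  globally average-pooled to a channel descriptor `s`, compressed to
  `z = relu(BN(W s))` with bottleneck width `d = max(C/r, 4)`, and a
  per-channel softmax over two branch logits yields weights `a + b = 1`
  that recombine the branches as `V = a U1 + b U2`. Exactly two branches
  are supported; the two-way softmax is computed as `a = sigmoid(l1 - l2)`,
  which is algebraically identical and numerically stable.

The decoder upsamples with 2×2 transposed convolutions (chosen over
bilinear upsampling so that every learnable stage is countable by the
closed-form parameter oracle in the tests), concatenates the
attention-refined skip, and applies another recurrent-residual block. A
1×1 convolution emits `K = 4` class logits per pixel (background, torso,
head, leg). Batch normalization follows every convolution; activations are
ReLU.

Because no deep-learning framework is assumed, the network runs on a small
reverse-mode automatic-differentiation engine written for this package:
channels-last (`H × W × N × C`) arrays, im2col convolutions through one
BLAS matrix product (with C++ gather/scatter inner kernels), and
hand-derived backward passes for every operator. Every backward pass is
validated against central finite differences, and the attention operators
against independent scalar loop oracles, in the test suite.

## Training

The loss is an equally weighted sum of per-pixel softmax cross-entropy and
soft multi-class Dice loss (smoothing 1e-6); it is non-negative and
approaches zero only in the perfect-prediction limit. The optimizer is
Adam at a constant learning rate. Production defaults mirror the intended
deployment configuration — 640×640 inputs, batch 8, 200 epochs, initial
learning rate 0.001 — while tests and examples use desk-scale overrides
(64×64, batch 4). All randomness (weight initialization, shuffling,
synthetic data) is derived from a single integer seed, and identical seeds
reproduce losses bit-for-bit; batch normalization keeps running statistics
so that inference (and checkpoint evaluation) is deterministic.

The **overfit harness** is the package's integration-level sanity check:
a depth-3, base-width-8 network with both attention mechanisms must fit 8
synthetic 64×64 images to a training-set mIoU of at least 0.90 within a
budget of 300 optimizer steps (evaluating every 10 epochs and stopping
early once the target is reached; at seed 1 it reaches mIoU 0.97 after 60
steps). This does not demonstrate generalization — only that the
architecture, gradients and optimizer are wired correctly.

## Evaluation metrics

All segmentation metrics are computed from one-vs-rest confusion counts
pooled over all pixels of all images (micro aggregation) before any ratio
is taken: `IoU = TP/(TP+FP+FN)`, `Dice = 2TP/(2TP+FP+FN)`,
`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. The identities
`Dice = 2·IoU/(1+IoU)` and (for binary masks) `F1 = Dice` are asserted
numerically to 1e-12. **mIoU averages IoU over the foreground classes**;
background is excluded by default (configurable) because including the
large, easy background class inflates the mean. Classes absent from both
prediction and truth are excluded from means; a class with error mass but
no overlap scores 0. Min–max normalization
(`x' = (x - min)/(max - min)`) is provided for cross-metric comparisons
and refuses constant vectors rather than guessing a convention.

## Stage two: morphometry and weight regression

Predicted masks are refined per class by **closing then opening**
(dilation–erosion, then erosion–dilation) with a structuring element,
default a disc of radius 5 px at 640 px inputs, scaled proportionally at
other resolutions (the element's size and shape are otherwise
unconstrained by the problem). Masks are zero-padded by twice the radius
beforehand so the image border behaves as background; the classes are then
recomposed under the fixed priority torso < leg < head, so a
higher-priority part keeps pixels contested after dilation. Per-part pixel
counts convert to areas as `area_cm2 = pixels / px_per_cm^2`; the
calibration is carried in the dataset manifest rather than detected from a
visual marker, whose geometry is out of scope.

Per-view areas (three replicates averaged, part groups summed) feed four
regression problems: **Mod1** overall area → total weight, **Mod2** torso
area → carcass weight, **Mod3** head area → head weight, **Mod4** leg area
→ leg weight; each uses the three views as three features. Five model
families are supported, each behind the same interface and tuned on the
validation split over a small fixed grid:

* `mlp` — single-hidden-layer perceptron (`nnet`, skip connections,
  linear output; sizes 4/8, decay 1e-4/1e-2),
* `svr_rbf` — ε-insensitive support vector regression with an RBF kernel
  (`e1071`; cost 1/10/100, γ 0.1/0.5/2, ε 0.01),
* `bayes` — Bayesian ridge regression with evidence-maximization
  hyperparameter updates, implemented in-package in SVD form so
  ill-conditioned (nearly collinear) view areas remain stable,
* `lgbm` — leaf-wise histogram gradient boosting (xgboost backend,
  `grow_policy = "lossguide"`, 31 leaves),
* `catboost` — depth-wise gradient boosting (xgboost backend,
  `grow_policy = "depthwise"`, depth 4/6).

The two boosting families run on xgboost because no native LightGBM or
CatBoost R binding is available in this toolchain; the names identify the
growth strategy each emulates. On noiseless synthetic data the
linearly-realizable families (`bayes`, `mlp`) reach R² ≥ 0.999; `svr_rbf`
plateaus near 0.97 because its ε-insensitive loss does not pursue exact
interpolation, and tree ensembles cannot extrapolate a linear trend — the
test suite therefore asserts exact recovery only for the realizable
families.

Reported scores are test-split `R² = 1 − SSres/SStot` and RMSE.
Uncertainty comes from a **percentile bootstrap** over (truth, prediction)
pairs (B = 1000 by default, seed-deterministic); in a simulation with a
known large-sample R² of 0.9 the nominal 95% interval covers the truth in
about 95% of replicates. Residual outliers are flagged at
`|residual| > 2σ`, with σ the sample standard deviation (n − 1) of the
residuals; on standard-normal residuals the flag rate is ≈ 4.6% in
expectation and the suite accepts 2–8%.

## The synthetic carcass generator

Real carcass images are proprietary, so the generator emulates the study
conditions: 301 carcasses × 3 views × 3 replicates (2709 images),
carcass-wise 8:1:1 split (floor(n/10) each to validation and test,
remainder to training: 241/30/30 at n = 301) with zero image-level
leakage.

Each carcass is a union of analytic primitives on a dark canvas — torso
ellipse, head disc, two leg capsules — laid out as a suspended carcass
(hung by the shanks, head down). Parts are tangent but never overlap, and
the two leg capsules stay mutually disjoint in every view, so every
per-part area has a closed form (πab, πr², 2(Lw + πw²/4)) against which
rasterized masks are checked. A pixel belongs to a part iff its center
lies strictly inside the shape; the same pixel-center convention drives
the Labelme polygon reader, so annotated and generated areas are
comparable. Views differ by fixed geometry multipliers (the lateral view
narrows the torso, offsets the head and nearly aligns the legs).
Replicates re-hang the bird with a Gaussian global translation
(`sigma_pos`, default 1.5 px); intensity is background ~N(20, σ_tex) and
foreground ~N(180, σ_tex) clipped to [0, 255] (σ_tex default 8). With both
sigmas zero, replicates are pixel-identical.

Across birds, a global scale `s ~ N(1, 0.08)` (clamped to [0.75, 1.3];
~8% CV is realistic for market-age broilers) and per-part log-normal
shape multipliers (sd 0.05) vary the geometry; the part-level jitter also
breaks the exact collinearity of part areas so that ordinary least
squares identifies the weight model. Weights follow a noisy linear
allometry: `total = β0 + Σ βp·Ap + N(0, σw)` with `Ap` the mean-over-view
part areas; part weights are generated analogously with fixed weight
shares (torso 0.82, head 0.05, leg 0.13) scaling intercept and noise, so
every Mod sees a comparable signal-to-noise ratio and the parts sum to
the total in the noiseless limit. Defaults (β0 = 150 g, β = 9/3/3 g/cm²)
give a mean total of ≈ 1180 g, plausible for a yellow-feathered broiler
carcass. σw = 61 g was calibrated once, from a 3000-carcass pilot of the
deterministic weight spread (sd 184 g), so the signal-variance fraction
of total weight is ≈ 0.9; under these conditions depth-wise gradient
boosting reaches a median test R² of ≈ 0.84 over 10 seeds (the model's
inability to extrapolate costs a few points against the 0.9 ceiling).

What the generator does **not** emulate: feathers and viscera, specular
or wet surfaces, camera optics, pose articulation, occlusion between legs
and torso in lateral views, and background clutter. Passing tests
therefore certify the correctness of the machinery — geometry, gradients,
metrics, calibration, statistics — not field performance on real
processing-line imagery.

## Numerical choices and degenerate inputs

* Softmax and cross-entropy are computed with row-max subtraction and a
  1e-12 probability floor; soft Dice uses a 1e-6 smoothing term.
* Batch normalization uses biased batch variance, momentum 0.1 and
  ε = 1e-5; the 1-D variant inside SK attention falls back to stored
  statistics for single-sample batches so oracle evaluations are
  deterministic.
* Max-pool and channel-max route gradients to the first maximum on ties.
* Mask PNGs store the label index directly in an 8-bit gray channel, so a
  write–read round trip is label-identical; class maps with duplicate
  values ("palette collisions") and labels missing from the class map are
  refused at write time.
* `minmax_normalize` errors on constant input; degenerate 0/0 metric
  ratios resolve to 0 when error mass exists and to NA (excluded from
  means) when a class is absent everywhere.
* Bootstrap resamples with zero target variance define R² = 1 when
  predictions are also exact, keeping the perfect-prediction interval at
  [1, 1].
* Geometry that cannot fit its canvas (including 4σ of re-hanging jitter)
  is rejected at generation time with the offending dimension named.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale:
attention oracles on ≤5×5×4 tensors (100 draws per operator), the overfit
harness on 8 64×64 images with a 300-step budget, regression on 120–301
synthetic carcasses, bootstrap coverage with 200 replicates of n = 80 at
B = 400, and a 12-carcass end-to-end pipeline run. These sizes were chosen
so the whole suite completes in minutes on a single CPU while still
exercising every code path at full fidelity.

## Known limitations

* The training loop is CPU-bound R; production-scale (640×640, 200-epoch)
  training is out of reach and out of scope.
* CBAM placement (skip connections) and the recurrence count follow the
  conventional reading of the architecture diagram; both are
  configuration switches, not claims.
* The linear-Gaussian weight model is a synthetic stand-in, not a claim
  about real birds; the area–weight relationship of an actual flock must
  be fitted from data.
* Carcass-level bootstrap CIs resample the test split only; they do not
  account for split-to-split variability.
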