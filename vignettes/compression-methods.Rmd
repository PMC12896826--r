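---
title: "Models and methods: single-frame behavior recognition and graph-based channel pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-frame behavior recognition and graph-based channel pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(herdprune)
```

## The problem

Collar-mounted sensors on free-grazing cattle produce a continuous
stream of inertial (accelerometer, gyroscope, magnetometer) and GPS
data. Classifying each observation window into a behavior — grazing,
lying, standing, walking, or finer ruminating/resting splits — enables
automated health and welfare monitoring at herd scale. Running the
classifier *on the collar* rather than in the cloud removes the radio
transmission that dominates the device's power budget, but the model
must then fit a microcontroller's compute envelope. `herdprune`
implements both halves of that problem: a compact single-frame residual
network classifier, and an automated structured-pruning search that
compresses it to a target fraction of its multiply–accumulate (MAC)
cost while preserving accuracy.

## Single-frame data model

One sample summarizes a 10 s window: the arithmetic means of the nine
IMU components sampled at 1 Hz, plus the great-circle displacement (km)
between the GPS fixes at the window ends, computed with the haversine
formula on a sphere of radius 6371.393 km. The ten features form a
1-channel sequence of length 10 — "single-frame data" — so the
classifier sees one vector per window instead of a sliding window of
raw samples, keeping both memory and MACs small. IMU units are
whatever the sensor reports; standardization makes the pipeline
unit-free, so units are documented rather than enforced.

## Preprocessing chain

The chain is SMOTE → split → standardize:

* **SMOTE.** Minority behaviors are oversampled by interpolation:
  `x_new = x + s (x_nn − x)`, `s ~ U(0,1)`, with `x_nn` one of the
  `k = 5` nearest same-class neighbors by Euclidean distance on the raw
  features. `k` and the neighbor metric are conventional defaults (the
  procedure's source leaves them open); both are arguments. Synthesizing
  before the split risks leakage between partitions of related synthetic
  points; we keep this order because augmentation is described before
  partitioning, and both orders are supported by calling the functions
  in the other order.
* **Split.** 7 : 3 train/test at the frame level; stratified by class
  by default (plain random splitting is available via
  `stratified = FALSE`).
* **Standardization.** Per-feature mean and *population* standard
  deviation (divisor `n`, exactly as the defining formula is printed)
  computed on the training partition only; all partitions share the
  training transform. A constant feature has `sigma = 0`; we floor
  `sigma` at `1e-8`, which maps such a column to zeros instead of
  dividing by zero.

## The S-ResNet classifier

`build_sresnet()` constructs: conv1 (1→32, kernel 3) → ResBlock 1
(32→64→64 with a kernel-1 shortcut) → ResBlock 2 (64→128→128, kernel-1
shortcut) → global average pooling → FC 128→64 → FC 64→C. Every
convolution is followed by batch normalization; ReLU follows conv1, the
first conv of each block, and each residual addition.

Choices the architecture description leaves open, fixed here:

* **Padding and stride.** Stride 1 with symmetric zero padding so the
  length-10 axis is preserved everywhere. This is forced by the residual
  additions (both branches must agree in length) and is consistent with
  the published MAC totals. The convention is recorded inside every
  `mac_report`.
* **MAC convention.** `count_macs()` counts kernel multiplies plus bias
  accumulations in conv and FC layers only; BN, activations and GAP are
  excluded. Under this convention the default model costs 1.040M MACs
  for both the 4-class and 6-class heads (the head difference is only a
  few hundred MACs and disappears at three decimals). Deployment
  toolchains that fold auxiliary ops into their counters report slightly
  different totals; those are a different convention, not a
  discrepancy.
* **Head activation.** The FC head is a plain affine composition
  (no ReLU between FC1 and FC2), matching the head's printed form;
  `head_relu = TRUE` toggles the alternative.
* **Softmax placement.** `predict_scores()` returns pre-softmax logits;
  probabilities come from `softmax_scores()` at prediction time only,
  and training uses softmax cross-entropy on the logits.
* **Initialization and BN.** Fan-in-scaled uniform weights
  (`U(±1/sqrt(fan_in))`), seeded; BN momentum 0.1, `eps = 1e-5`,
  evaluation mode uses running statistics. Because every convolution is
  immediately batch-normalized, the conv bias is absorbed by the BN
  statistics (its gradient through BN is exactly zero); it is kept as a
  parameter because the MAC convention counts its accumulations.
* **Training.** Adam, learning rate 0.001, batch 128, cross-entropy,
  100 epochs by default; fine-tuning after pruning reuses the same
  loop and hyperparameters starting from the pruned weights. Runs are
  deterministic given the config seed. No dropout or weight decay
  (none are specified; both absent by default).

The forward/backward pass is written in R matrix algebra over
`(channels × length·batch)` activations, with the kernel-3 column
unfolding and fused bias+BN elementwise passes in C++ (`src/`), and all
matrix products in BLAS. Gradients are verified against central finite
differences in the test suite.

## Structured pruning environment

Pruning removes whole input channels, so the pruned network stays dense
and runs on any hardware. The residual wiring couples layers into five
decision groups (`coupling_groups()`): the inputs of each block's first
conv and shortcut are pruned together (removing the upstream producer's
filters), the block-internal conv input is its own group, and at each
residual addition the block's second conv and shortcut are pruned
*jointly* so the addition stays aligned — their importance scores
accumulate across both weight slices. conv1's input is the sensor frame
itself and is never pruned; the head's 64-dim FC1→FC2 interface is not
a channel interface and is likewise untouched.

* **Importance.** Channel `m`'s score is the L2 norm of the
  concatenation of every consumer's weight slice for input `m`;
  channels are kept in descending score order.
* **Rounding.** A retention `R` keeps `ceil(R · c_in)` channels,
  floored at `ceil(r_min · c_in)` with `r_min = 0.2`; `ceil` avoids
  channel collapse at small widths. Kept channels preserve their
  original order, so `R = 1` is bit-identical. Retention is reported as
  the kept fraction `c_in' / c_in` throughout (one printed sentence in
  the source material inverts this definition; we treat that as an
  erratum).
* **Budget enforcement.** The optimization constraint (pruned MACs ≤
  `R_target` × original) states no mechanism. We use the bounded-action
  scheme standard in RL channel pruning: before executing a decision,
  `feasible_action()` clamps it to the largest retention that still
  admits a feasible completion with all remaining groups at `r_min`.
  An infeasible budget errors at episode start, never mid-episode. The
  per-channel state rows carry `reduced` (MACs already removed) and
  `rest` (MACs of still-undecided layers) precisely to expose this
  bookkeeping to the agent; the three quantities partition the original
  total at every step (audited in tests).
* **State.** One row per channel:
  `[l, t, c_in, c_out, stride, k, Wprod, Wnorm, reduced, rest, R_prev]`,
  with `t` a layer-type code, `Wprod` the channel's parameter count and
  `Wnorm` its weight norm; FC consumers are described with `k = 1`,
  stride 1, output length 1. Columns are min-max scaled to [0, 1] with
  bounds fixed at episode start (static columns from the unpruned
  model's groups; `reduced`/`rest` by the MAC total; `R_prev` by
  [0, 1]) — unscaled states of very different magnitudes destabilize
  GCN training.
* **Reward.** Zero at every non-terminal step; at the terminal step,
  held-out accuracy × `reward_scale`. The procedure's two statements of
  the scale disagree (0.1 in prose, 0.01 in the algorithm listing); the
  default follows the algorithm listing and the argument exposes both.
  The reward accuracy is computed on a validation split never used for
  weight updates. No fine-tuning happens inside the search; the best
  strategy is fine-tuned once afterwards.

## The GCN actor–critic and TD3

Each decision state is a graph over the group's channels. The edge rule
is unspecified beyond "closely related channels"; we connect each
channel to its `k_nn = 5` most cosine-similar channels (by flattened
weight slice), symmetrize, and add self-loops — cheap, deterministic,
and a direct reading of weight-similarity as relatedness. Graph
convolutions use the symmetric normalization
`D^{-1/2} (A + I) D^{-1/2}`.

The actor is GCN(11→400) → GCN(400→300) → GCN(300→1) with ReLU between
layers, mean-pooled over nodes and squashed by a sigmoid into (0, 1).
Mean pooling (rather than sum) keeps the pooled scale independent of
the group width, which varies 32–128 across decisions. Each critic
embeds the graph through one GCN layer mean-pooled to 400 dims, maps
the scalar action to 400 dims with an affine layer, fuses the two by
elementwise sum ("mapped to the same dimensionality … combined" read as
additive fusion), and regresses 400→300→1. Output layers of actor and
critics are initialized `U(±3e-3)`, the classic deterministic-policy-
gradient recipe: rewards are of order 0.01, and a fan-in-scaled output
layer would make the untrained critics' values orders of magnitude
larger, sending the early actor chasing value noise into an action-space
corner (we observed exactly this before adopting the small output
initialization).

TD3 proper: uniform random actions for the first `T1 = 100` of
`T = 600` episodes; afterwards truncated-Gaussian exploration noise on
`[a, b] = [r_min, 1]` around the actor output, scale `delta1 = 0.25`
decaying ×0.99 per episode. One mini-batch update (N = 64) per episode
at the terminal step: both critics regress to
`y = r + gamma·min(Q'_1, Q'_2)` with target-policy smoothing noise
`N(0, delta2 = 0.1)` added to the target action and *clipped back to
[a, b]* (an unbounded target action would be an invalid retention);
the bootstrap term is dropped at terminal transitions (episodes are
finite-horizon). Every second update the actor ascends `dQ_1/da` and
all targets soft-update with `tau = 0.01`. Discount `gamma = 0.99`,
buffer capacity 10 000 with FIFO eviction; these, like the noise
parameters, are conventional defaults where the recipe is silent, and
all sit in `td3_config()`. A single actor is shared across all layer
decisions (the update listing uses one policy). The search returns the
episode with the highest terminal reward and can checkpoint/resume.

## The synthetic herd generator

No public deposit of the original collar data exists, so
`generate_synthetic_herd()` emulates its structure: class-conditional
sensor windows with a per-frame posture offset (between-animal and
posture variability), 1 Hz within-window noise, and displacement
realized as an actual pair of GPS fixes at a random bearing — so frames
pass through the same `assemble_frame()` path as real data. The default
emission parameters encode the field structure that drives real
classifiers: walking displaces an order of magnitude farther per window
(~14 m) than grazing (~3 m), while standing and lying displacements are
GPS jitter; lying has a distinct collar orientation; standing shares
posture with grazing's head-up moments and displacement with lying,
deliberately reproducing the standing→grazing/lying confusion pattern
seen in collar studies. Class proportions are imbalanced (walking
rarest) so the oversampling step is exercised. Displacement scales are
set from typical bovine locomotion speeds; IMU means and spreads were
chosen once so that the 4-class task is learnable to high accuracy yet
not trivially separable in any single IMU feature.

What the generator does *not* emulate: sensor drift and outliers,
autocorrelation between consecutive windows of the same animal,
individual-animal identity (frames are exchangeable), label noise, and
magnetometer dependence on heading. Tests passing on synthetic data
therefore validate the algorithmic machinery — preprocessing
correctness, architecture arithmetic, budget guarantees, search
behavior — not field-data accuracy levels.

## Validation problem sizes

The packaged end-to-end checks run at desk scale, chosen as the
smallest sizes at which each claim is meaningful: the compression
retention check uses 4 000 generated frames, 15 training epochs, a
60-episode search (20 exploration) at `R_target = 0.5`, and 20
fine-tuning epochs across 5 seeds; the policy-recovery check uses a
two-decision toy environment with a known analytic optimum (Gaussian
accuracy peak at retentions (0.7, 0.4), width 0.22, terminal reward
accuracy × 0.01), a 0.05-grid exhaustive oracle, and 200-episode
searches across 10 seeds; the budget guarantee is exercised over 500
random-policy episodes at three targets. Full-scale defaults (100
epochs, 600 episodes) remain the function defaults.

## Numerical choices and degenerate inputs

Haversine clamps its argument into [0, 1] before `asin` (guarding
rounding at antipodes) and rejects non-finite or out-of-range
coordinates. BN variance is clamped at 0 before adding `eps`.
Cross-entropy clips probabilities at `1e-12` inside the log.
Prediction ties break toward the lowest class index, making runs
bitwise reproducible. Zero-denominator sensitivities/precisions are
reported as `NA`, never 0. Cohen's kappa defines the `p_e = 1` case
(both raters constant and identical) as 1. The truncated-normal
sampler uses the inverse-CDF construction and clamps `qnorm` edge
cases back into the interval.

## Known limitations

* Training is CPU-bound R + BLAS; it is sized for length-10 frames and
  ~10^2k-parameter models, not for image-scale networks.
* The environment's coupling-group derivation is specific to the
  two-block S-ResNet topology; other residual families would need
  their own group builder (the environment contract itself is
  architecture-agnostic).
* One mini-batch update per episode (as the update listing prescribes)
  learns slowly at small episode counts; short searches lean on the
  exploration phase plus the best-episode bookkeeping.
* Synthetic-data accuracy levels say nothing quantitative about field
  data (see the generator section).
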