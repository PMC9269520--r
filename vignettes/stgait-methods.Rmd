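---
title: "Recognizing pathological gait on skeleton graphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing pathological gait on skeleton graphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgait)
```

# The problem

Pathological gaits — antalgic, lurch, steppage, stiff-legged and
Trendelenburg patterns, against a normal control — express musculoskeletal
or neurological impairment in the way the whole body moves. Given a 3D
skeleton sequence (T frames of V = 25 Kinect-V2 joints), the task is to
classify the walk. `stgait` implements a multiple-input-branch
spatiotemporal graph convolutional network (MIB ST-GCN) for this task,
together with the feature algebra that feeds it, a leave-one-subject-out
(LOSO) evaluation protocol, class-activation maps on the skeleton, and a
kinematic simulator of the six gait classes so that the entire pipeline is
runnable and testable without any external data.

# Skeleton graph and adjacency algebra

The skeleton is an undirected tree: V joints, V − 1 bones, rooted at the
SpineMid center joint. The binary adjacency `A` has `A[i,j] = 1` exactly for
connected joint pairs. The graph convolution consumes the self-loop
augmented, symmetrically normalized matrix

$$A_{norm} = \tilde D^{-1/2} (A + I) \tilde D^{-1/2},$$

whose entries lie in [0, 1] and whose spectral radius is 1, so repeated
application cannot blow features up.

For the spatial-configuration partitioning (the default; uni-label and
distance partitionings are selectable), every nonzero of `A + I` is assigned
to exactly one of K = 3 groups that receive separate convolution weights:
the self-loops; centripetal connections, pointing to a neighbor at most as
close to the center joint (hop distance, ties centripetal); and centrifugal
connections, pointing farther away. Each partition mask is normalized
symmetrically with degrees taken over the partition's *symmetrized* support.
This detail matters: the centripetal/centrifugal masks are directional, and
normalizing them with their own row or column degrees alone would divide by
zero for entries whose endpoint has no outgoing member in the same
partition, silently deleting connections. With symmetrized-support degrees
every connection survives, the three supports tile the support of `A + I`
exactly, and for symmetric masks the rule reduces to the usual
$D^{-1/2} M D^{-1/2}$ — so the uni-label partition equals `A_norm` exactly.

# The three input branches

From the positions $x_i(t)$ the package derives three 6-channel streams
(each 6 × T × V):

* **joint** — absolute coordinates stacked over center-relative coordinates
  $r_i = x_i - x_{center}$;
* **velocity** — one-frame displacements $v^{(1)}_t = x_{t+1} - x_t$ stacked
  over two-frame displacements $v^{(2)}_t = x_{t+2} - x_t$ (trailing
  undefined frames zero-filled so every stream keeps the same T);
* **bone** — parent-pointing bone vectors $b_i = x_i - x_{parent(i)}$
  stacked over their componentwise direction angles
  $a_i = \arccos(b_i / \lVert b_i \rVert)$, clamped to [−1, 1] before the
  arc-cosine to absorb floating-point overshoot. The root joint takes the
  zero bone and the neutral angle $\pi/2$, avoiding NaNs.

Both velocity differences are kept, concatenated, which makes all three
branches 6-channel and symmetric in shape. Translation of the whole skeleton
moves only the absolute-coordinate channels; relative, velocity and bone
channels are exactly invariant, and absolute positions are recoverable from
the root trajectory plus bone vectors (both properties are tested). No view
alignment or pre-rotation is applied before the relative-coordinate step:
the simulator emits a single canonical camera frame, and the network's input
normalization absorbs global offsets.

# Network architecture

Each branch is processed by its own stack: input batch normalization over
the flattened channel-joint axis, an initial ST-GCN block (no attention) and
three attention-equipped ST-GCN blocks. The three branch outputs are
concatenated along channels and sent to a two-block mainstream whose first
temporal layer in each block strides by 2 (compressing T by 4 overall). A
global average pool over frames and joints feeds a fully connected layer
that emits the class logits.

One **ST-GCN block** is: spatial graph convolution
$\sigma(\sum_k A_k X W_k + b)$ with one weight matrix per partition;
`blockDepth` temporal convolutions (kernel × 1 along the frame axis,
symmetric zero padding, the first possibly strided); a residual connection
from the block input (1×1-projected when the width or temporal length
changes, identity otherwise); a rectifier; and the spatiotemporal joint
attention gate.

**Normalization.** The lineage this architecture belongs to normalizes
after every convolution, and our experiments reproduce why: without
internal normalization the 14-block stack trains erratically — activation
scales drift across the residual stream, and some seeds collapse into
partial solutions that never recover. Every convolution output (graph,
temporal, and residual projection) is therefore standardized per channel —
batch moments during training, running moments at evaluation, with the
layer bias applied after the standardization (a learnable per-channel gain
would be absorbed by the next convolution, so none is used). Running
moments are tracked with momentum $\max(0.1, 1/(n+1))$, which makes the
first updates a cumulative average so evaluation statistics lock on
quickly.

**Attention.** The spatiotemporal joint attention pools the feature map
over joints (a C × T frame descriptor) and over frames (a C × V joint
descriptor), compresses the concatenated descriptors through a shared
C → C/r bottleneck (rectified), maps back to C through two independent
heads, and squashes with a sigmoid. The input is gated by the channel-wise
outer product `M[c,t,v] = frame[c,t] · joint[c,v]`. The sigmoid keeps
scores strictly inside (0, 1); forcing both score sets to 1 reproduces the
attention-free block bit for bit, which is the ablation contract the tests
pin down. Attention output biases are initialized at 3 (gates ≈ 0.95), so
a freshly built block behaves almost like its attention-free ablation and
the gates engage as the heads learn — with mid-range initial gates the
multiplicative path destabilized early training. The compacting
nonlinearity is a rectifier.
Attention sits in the three upper branch blocks by default; a configuration
flag extends it to the mainstream.

**Separable temporal convolution.** Temporal layers default to the
depthwise-separable factorization — one kernel-tap filter per channel
followed by a 1×1 channel-mixing convolution — with
`kernel·C + C·C_out` weights against `kernel·C·C_out` for the standard
form (4672 vs 36864 at C = C_out = 64, kernel 9). A switch restores the
standard convolution for comparison.

**Initialization.** He-scaled Gaussian weights throughout, including the
classifier head (see the benchmark section for why a zero-initialized head
is avoided).

## Dimensions and defaults

The full-size configuration (`modelConfig()`) uses per-branch widths
64-32-32-64 (a bottleneck that keeps the model compact), mainstream widths
128 and 256, temporal kernel 9 and two temporal layers per block. The
printed sources for this architecture family do not state the exact channel
numbers, the initial block's composition, or the residual's
projection-vs-identity rule at equal shapes; the defaults above are
declared package choices, all configurable. The residual uses the identity
wherever shapes agree and a 1×1 strided projection otherwise.

# Optimization

Training minimizes softmax cross-entropy with Adam over shuffled
minibatches, weight decay 1e-4, and a step-decay schedule (rate quartered
after 60% and again after 85% of the epochs). Everything is seeded: weight
initialization from the model configuration's seed, shuffling from the
training seed, and the simulator from its own seed, so identical calls give
bit-identical results.

# The gait simulator

The simulator is a stylized kinematic oscillator, not a biomechanical
model. A pelvis root advances at the stride cadence; hip and knee angle
profiles (knee flexion confined to the swing phase) drive the legs through
rigid segment rotations; arms swing in anti-phase. Because every joint is
placed by forward kinematics from fixed segment vectors, bone lengths are
constant over time until Gaussian sensor noise (default 5 mm, Kinect-like)
is added — a property the tests verify at noise 0. Its contract is only
that each class's clinical signature is injected where clinicians describe
it, scaled linearly by a severity in [0, 1]:

* **antalgic** — the affected leg's stance duty factor shrinks (piecewise
  phase warp of that leg's cycle);
* **lurch** — backward trunk pitch during affected stance;
* **steppage** — amplified affected-side hip flexion and knee lift;
* **stiff-legged** — affected knee flexion suppressed plus a lateral
  circumduction arc of the whole leg;
* **Trendelenburg** — lateral trunk (and partial pelvis) roll toward the
  affected side during its stance.

At severity 0 all six classes collapse onto the identical normal walk for a
given seed and anthropometry, which enables the negative-control experiment
(a classifier trained on severity-0 data must score at chance). The
class-defining statistics (duty asymmetry, trunk pitch/roll range, foot
lift, knee flexion range) are monotone in severity by construction and
tested as such.

Datasets emulate a multi-subject study: each subject draws a limb scale in
[0.9, 1.1], a cadence in [0.8, 1.0] Hz, amplitude habits, and an affected
side; each trial adds a random starting phase, ±5% amplitude jitter and
sensor noise. Affected sides are **balanced** across subjects (randomized
order): under leave-one-subject-out evaluation every training set must
contain both lateralities, otherwise a held-out subject carrying a
minority side would pose an extrapolation problem — the fold would measure
generalization to a covariate level never seen in training rather than
gait-pattern recognition. This is the standard balanced allocation for a
binary subject-level covariate in a small-cohort design.

What the simulator does *not* emulate: ground contact and reaction forces,
multi-camera geometry and occlusion, marker dropout, within-subject
day-to-day variability, and correlated (non-Gaussian) sensor error. Passing
the synthetic benchmark therefore demonstrates that the implementation
learns and explains the class signatures it was given under realistic
noise and anthropometric variation — not that it reaches any particular
accuracy on clinical recordings.

# Evaluation protocol and the synthetic benchmark

Evaluation is leave-one-subject-out: one fold per subject, the fold's test
set exactly that subject's samples, so train and test subjects are always
disjoint. The pooled confusion matrix across folds yields the reported
accuracy; per-fold accuracies (and their mean) are reported alongside,
since with balanced class counts per subject the two coincide up to
rounding.

The synthetic benchmark trains the reduced configuration
(`benchmarkModelConfig()`: branch width 8, mainstream 16 then 64, kernel 5,
one temporal layer per block) on 8 subjects × 6 classes × 10 trials of
64-frame simulated sequences at severity 0.7 and 5 mm noise, downsampled to
32 frames (15 fps) at the network input — the gait signatures live far
below that Nyquist limit, and validation showed the same leave-one-subject-
out accuracy at 32 as at 64 input frames under identical recipes. The
mainstream *widens* into its final block (16 → 64): global average pooling
hands the classifier one number per channel, so the final width bounds how
many joint- and phase-selective statistics survive the pooling, and that
block runs at a quarter of the input length where width is cheap.

Training runs 14 epochs of Adam at rate 0.05, batch 64 (large enough for
stable batch moments at every normalization site), weight decay 5e-4,
dropout 0.3 on the pooled classifier features, with the rate quartered
after epochs 9 and 12. The classifier head is initialized at random He
scale: a zero-initialized head starts all class logits identical, and with
hard class pairs this proved to seed a basin where the pair's features
never differentiate. All of these sizes and the single-replicate in-suite
harness (the acceptance script re-runs the same benchmark at any seed) are
the package's own choices, set so the full LOSO × ablation harness runs in
minutes on a single CPU; the negative-control training is shortened to 4
epochs because its conclusion — chance accuracy on severity-zero data —
does not depend on training length. Everything is deterministic in the
seeds, so the reported accuracies are exactly reproducible.

# Class-activation maps

Because the classifier is a linear map of globally averaged features, the
weighted channel sum $M(t, v) = \sum_c w^{(class)}_c F_c(t, v)$ over the
mainstream's final (post-attention) feature map scores how much each frame
and joint drives a class logit. The map is rectified at zero (negative
evidence discarded, matching the positive-saliency reading) and normalized
to sum to one; an all-zero rectified map returns the uniform map with a
warning. The temporal grid is the final feature map's (T/4 after the two
stride-2 layers); nearest-neighbor upsampling maps it back to input frames
for visualization. The map is invariant to positive rescaling of the
classifier weights and to bias shifts, and per-joint importance is the
frame-summed mass.

# Numerical and engineering choices

* Joint indices are 1-based inside R; edge-list files use the 0-based
  convention with a `V=<n> center=<c>` header.
* The arc-cosine argument is clamped to [−1, 1]; zero-length bones take
  angle $\pi/2$.
* Prediction ties at equal logits resolve to the lowest class index.
* Training and batch prediction run through a single-precision compiled
  batched engine (`src/netbatch.cpp`); a pure-R double-precision reference
  implementation of every layer remains in the package and serves as the
  oracle in the test suite — gradients are verified against finite
  differences, and the two engines are compared directly on random inputs.
  Exported single-map operations and CAM use the reference path.
* Sequence containers are R-native serialized files (one record per sample:
  positions plus subject/class/fps attributes, optional cached branch
  features); single sequences and activation maps export to plain CSV.
* Resampling to a common length is linear interpolation with exact
  endpoints; the default benchmark length is 64 frames (about two gait
  cycles at the simulated cadences).

# Known limitations

* The simulator's stylization means absolute accuracies on it say nothing
  quantitative about clinical data; only the qualitative contracts (class
  signatures, ablation direction, negative control) transfer.
* Learnable edge-importance masks on the adjacency are available only in
  the reference engine (training with them falls back to the slower path).
* The attention analysis (CAM) is the classifier-weight projection; no
  gradient-based attribution is provided.
* Single-body sequences are assumed downstream of the reader; the NTU
  reader keeps the best-tracked body per frame and repeats the nearest
  observed frame across gaps, with a warning.
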