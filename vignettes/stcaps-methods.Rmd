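---
title: "stcaps: methods, design decisions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stcaps: methods, design decisions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stcaps)
```

## The decoding problem

`stcaps` classifies single EEG epochs into two cognitive conditions —
perception (class 1, the positive class) versus imagination (class 0)
of a semantic concept. The canonical recording geometry it targets is
124 scalp channels sampled at 1024 Hz, with visual epochs standardized
to 3 s (3073 samples, `round(3·1024)+1`) and auditory epochs to 2 s
(2049 samples). Epochs travel through the package as `eeg_epoch_set`
objects: a `(trials, channels, samples)` array with binary labels and a
sampling rate.

## Model

### Capsules and the squash nonlinearity

A capsule is a small vector of neurons: its Euclidean norm encodes the
probability that a feature is present, its direction encodes the
feature's attributes. Norms are mapped into `[0, 1)` by

$$\mathrm{squash}(s) = \left(1 - e^{-\lVert s\rVert}\right)
  \frac{s}{\lVert s\rVert},$$

which preserves direction and is strictly increasing and bounded in the
input norm. At the origin this expression is 0/0; the continuous
extension `squash(0) = 0` is the only consistent choice and is
implemented with an epsilon-guarded norm (series expansions take over
below `1e-8` in the forward and `1e-3` in the derivative, where the
closed forms lose precision to cancellation).

### The STCG front-end

The spatio-temporal capsule-generation block maps a raw epoch to `n`
primary capsules of dimension `d` through five convolutions and two
poolings (see `stcg_plan()` for the symbolic shape table):

| stage | operation | kernel | role |
|---|---|---|---|
| 1 | temporal conv, `F1` filters | `(1, TI)` | oscillatory band features |
| 2 | spatial depthwise conv, multiplier `D` | `(C, 1)` | scalp-topography mixing; collapses the channel axis |
| 3 | average pooling | `(1, pool1)` | temporal redundancy reduction |
| 4 | depthwise separable conv (`(1,16)` depthwise + `F2` pointwise) | | local temporal patterns + cross-map mixing |
| 5 | average pooling | `(1, pool2)` | further reduction |
| 6 | depthwise fusion conv spanning the residual extent | `(1, T₆)` | one scalar per map; reshaped to `(n, d)` capsules |

Average (not max) pooling is used deliberately: for continuous brain
signals pooling serves redundancy reduction, not detection. The fusion
layer's output has temporal length 1, so the capsule reshape is exact
iff `F2 = n·d`; `model_config()` enforces this arithmetic and reports
the failing numbers otherwise.

Several front-end sizes are free parameters of the architecture family
rather than fixed constants. The package's defaults — `F1 = 16`,
`D = 2`, `F2 = 64`, `TI = 65` samples, pooling widths 4 and 8,
`n = 8` capsules of dimension `d = 8` — were chosen once so that the
five-conv/two-pool skeleton closes numerically on both the 3073- and
2049-sample geometries, following the conventions of
depthwise-separable EEG front-ends (temporal kernel of roughly 1/16 s,
depth multiplier 2). All are exposed in `model_config()`. Batch
normalization + ELU follow convolutions 1, 2 and the pointwise stage
(`batch_norm = FALSE` disables them); this is the standard
accompaniment of such front-ends and measurably stabilizes margin-loss
training at learning rate 0.02.

### Self-correlation routing

The primary capsules `U` are coupled to the two class capsules in one
fixed, non-iterative pass:

1. **Prediction**: `Û[i,j,·] = U[i,·] W[i,j,·,·]`, with a learnable
   tensor `W` of shape `(n_l, n_{l+1}, d_l, d_{l+1})`.
2. **Self-correlation tensor**: for each output capsule `j`, the Gram
   matrix `A[·,·,j] = Û[·,j,·] Û[·,j,·]ᵀ / d_l` — pairwise similarity of
   the predictions, symmetric in its two input-capsule axes.
3. **Coupling coefficients**: logits `L[i,j] = Σ_k A[i,k,j]`, then a
   softmax across output capsules, so `Σ_j C[i,j] = 1` for every input
   capsule.
4. **Aggregation**: `S[j,·] = Σ_i Û[i,j,·] (C[i,j] + B[i,j])` with a
   learnable log-prior matrix `B`, then squash.

Two renderings of this mechanism are genuinely ambiguous, and both are
configurable:

* **Gram scaling** — the tensor is divided by `d_l` (the printed form,
  the default) or by `√d_l` (the attention convention);
  `corr_scale = "sqrt_dl"` selects the latter.
* **Output squash** — the aggregated class capsules are squashed by
  default (`squash_output = TRUE`), because the margin loss and the
  magnitude-as-probability reading both require norms in `[0, 1]`.

The class-capsule dimension defaults to `d_out = 16` (the conventional
digit-capsule size); `B` initializes at zero — no initial bias between
capsule pairs — and `W` from fan-in-scaled normals (`sd = 1/√d_l`),
both seeded.

### Dynamic-routing baseline and the traditional front-end

For ablations the package ships the classic iterative
routing-by-agreement: zero-initialized logits, then per iteration a
softmax coupling, a coupling-weighted prediction sum, a squash, and a
logit update by prediction–output dot products (the update runs in
every iteration, as the reference algorithm prints it). Backpropagation
unrolls the iterations exactly. The "traditional capsules" ablation
front-end is two standard square-kernel (3×3, stride 2) convolutions
with ELU, global average pooling, and a capsule reshape matched to
`n·d` outputs — the minimal square-kernel instantiation at matched
capsule geometry.

### Objective and metrics

Training minimizes the margin loss on class-capsule norms,

$$\zeta_n = T_n \max(0, m_+ - \lVert u_n\rVert)^2 +
  \lambda (1 - T_n) \max(0, \lVert u_n\rVert - m_-)^2,$$

summed over classes and averaged over the batch (mean reduction keeps
learning-rate semantics independent of batch size). The margins default
to the canonical capsule settings `m_+ = 0.9`, `m_- = 0.1`,
`λ = 0.5`. Accuracy is `(Tp+Tn)/(Tp+Tn+Fp+Fn) × 100` with perception
as the positive class; prediction is the argmax of capsule norms with
ties broken toward the lower class index.

### Optimization

Adam at learning rate 0.02, batch size 20, 120 epochs by default; no
schedule and no early stopping. All gradients — through every
convolution, batch norm, pooling, squash, both routing mechanisms, and
the loss — are hand-derived and validated against central finite
differences to ~1e-9 relative error in the test suite (entries whose
true gradient is exactly zero, such as convolution biases absorbed by a
following batch norm, are compared with an absolute floor).

## Synthetic data

No public epoch data ships with the package; `generate_epochs()`
provides seeded, class-separable stand-ins with the target geometry.
Each class owns a fixed template: a random spatial mixing matrix
(channels × sources, unit-variance normals scaled by `1/√S`) applied to
band-limited oscillatory sources (frequencies uniform in the configured
passband, default 4–30 Hz; class-specific amplitudes, phases, and a
slow amplitude envelope), normalized to unit mean-square power. A trial
is its class template plus spatially correlated 1/f noise scaled
exactly to the configured SNR, defined as
`10·log10(signal power / noise power)` averaged over channels;
`snr_db = Inf` disables noise so every trial equals its template. Class
structure therefore lives in *both* the spatial mixing and the source
dynamics, exercising both the `(C, 1)` spatial and `(1, TI)` temporal
convolution pathways.

What this emulates: the geometry, the oscillatory band-limited
character of EEG, its 1/f background and inter-channel correlation, and
a controllable class separation. What it does not: per-trial latency and
amplitude variability of real evoked activity, artifacts (blinks, EMG),
non-stationarity across a session, volume-conduction physics, or any
statistical property of real semantic-decoding data. Passing the
recovery tests therefore demonstrates that the implementation can
extract genuinely present spatio-temporal class structure end to end —
not that it attains any particular accuracy on real recordings.

## Numerical and protocol choices

* **Sample counts** are `round(duration·sfreq) + 1` so 3 s at 1024 Hz
  gives exactly 3073 samples.
* **Cropping** (`crop_to_duration()`) keeps the leading, stimulus-locked
  samples — the conventional epoching choice.
* **Same padding** for temporal convolutions: `(TI−1)/2` left (odd
  kernels); the even `(1, 16)` depthwise kernel pads 7 left / 8 right.
  Pooling truncates a non-divisible trailing remainder.
* **Softmax** logits are stabilized by max-subtraction
  (value-preserving; the summed Gram logits grow with `n_l`).
* **Hold-out default** where cross-validation is not requested: a
  seeded, stratified 80/20 split. Stratified `k`-fold plans keep
  per-fold class counts within one trial of proportionality.
* **Container format**: epoch sets serialize as a compressed named-array
  archive (`data`, `labels`, `sfreq`, `modality`) via R's native
  serialization; the round trip is lossless.
* **Complexity accounting** (`count_complexity()`) is analytic:
  1 MAC = 2 FLOPs, element-wise extras at one FLOP per scalar
  operation, parameters counted exactly (the test suite checks totals
  against the realized parameter vectors). One consequence worth
  stating plainly: self-correlation routing costs
  `O(n_l² n_{l+1} d_{l+1})` for its Gram tensor in a single pass, while
  dynamic routing costs `O(R · n_l n_{l+1} d_{l+1})` over `R`
  iterations. With few capsules (`n_l` below roughly `2R`) dynamic
  routing is the more expensive mechanism — approaching twice the cost
  at `n_l = 2` — whereas for many capsules the quadratic Gram term
  dominates and the ordering reverses. The package reports both counts
  rather than a single verdict.

## Problem sizes used by the test suite

CPU-scale experiments run on the `reduced_config()` preset — 8
channels, 128 samples (1 s at 127 Hz), `F1 = 8`, `TI = 33`, 4 capsules
of dimension 4, `d_out = 8` — with 100 trials per class at 10 dB SNR,
30 training epochs for the recovery check and 20 per fold for 5-fold
cross-validation. These sizes are the package's chosen study
conditions for demonstrating end-to-end learning; the full-geometry
configuration is exercised for shape conformance and forward passes.

## Known limitations

* Pure-R tensor operations are CPU-bound; the full 124×3073 geometry is
  practical for inference and shape checks but slow to train at 120
  epochs. The architecture is deliberately expressed in portable base R
  rather than a GPU framework.
* One routed capsule layer (primary → class) is implemented; the
  mechanism generalizes to stacked capsule layers but the package does
  not provide them, nor EM routing.
* The generator is a forward-model stand-in, not a fitted model of any
  real dataset; absolute accuracies on it do not transfer to real EEG.
* EDF import is not provided; real recordings must be converted to the
  package's epoch container externally.
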