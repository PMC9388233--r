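---
title: "BrainSeg3D: model, enhancement mathematics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BrainSeg3D: model, enhancement mathematics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BrainSeg3D)
```

## What the package does

BrainSeg3D segments brain tumors and their subregions from co-registered
multimodal 3D MRI (Flair, T1, contrast-enhanced T1, T2, the BraTS case
layout). The pipeline has two halves:

1. a deterministic per-slice **enhancement model** — wavelet
   decomposition, optional deflation-PCA compression of the detail
   bands, and a covariance-whitened matched filter that produces a
   per-voxel tumor-energy map — and
2. a trainable **3D attention U-Net** that consumes the enhanced
   modalities plus the energy map and emits a per-voxel label in the
   BraTS convention (1 = necrotic/non-enhancing core, 2 = edema,
   4 = enhancing tumor), from which the nested evaluation regions
   ET $\subseteq$ TC $\subseteq$ WT are derived.

Because the real BraTS data are access-controlled and full-scale
training needs GPU hardware, every stage is exercised on synthetic
multimodal phantoms with known ground truth. The phantom generator is
first-class, tested code, and the package's acceptance checks are
property-based: exact identities of the mathematics, gradient
correctness, and segmentation recovery on phantoms.

## The enhancement model

### Per-slice wavelet stage

Each axial slice of each channel is decomposed by a separable
orthonormal discrete wavelet transform with periodic boundary handling
(Haar by default, Daubechies-2 available), giving an approximation band
$W_\varphi$ at the coarsest scale and horizontal/vertical/diagonal
detail bands $W^i_\psi$, $i \in \{H, V, D\}$, at every scale. The
transform is implemented as an explicit orthogonal analysis matrix per
axis, so two properties hold to machine precision and are asserted in
the tests: energy conservation (Parseval) and perfect reconstruction by
the transposed matrix. Normalization constants of the continuous-form
transform are absorbed into the orthonormal filter normalization — that
is the only convention under which analysis followed by synthesis is
exactly the identity, which is the property the pipeline relies on.

Slice dimensions must be divisible by $2^{\mathrm{levels}}$; the default
is a single level. BraTS-sized slices (240 x 240) support up to four
levels.

### Deflation PCA across the slice stack

The detail bands of all slices of one channel are flattened into a
matrix (one row per slice) and compressed by **deflation PCA**:
components are extracted sequentially, each maximizing
$\lVert \hat X_i w \rVert^2$ over unit vectors $w$ on the deflated
matrix $\hat X_i = X - \sum_{s<i} X w_s w_s^T$. This sequential
procedure is algebraically equivalent to the dominant eigenvectors of
the centered $X^T X$; the package asserts that equivalence against a
dense eigendecomposition, together with the score-covariance identity
$Q_{jk} = (Xw_j)^T(Xw_k) = \lambda_k\, w_j^T w_k$ (diagonal with the
eigenvalues on the diagonal).

The maximization runs by power iteration with explicit
re-orthogonalization; when the feature dimension exceeds the number of
slices the iteration runs in the dual (Gram) space, which is the same
maximization at a fraction of the cost. Components have a deterministic
sign convention (largest-magnitude loading positive). When the data
variance is exhausted before `k` components the basis is completed with
arbitrary orthonormal directions, zero eigenvalues, and a warning.

Compression keeps `pcaK = 8` components by default — enough to retain
the dominant detail structure of a 64-slice stack while discarding
slice-wise noise; `usePCA = FALSE` makes the wavelet stage lossless.

### Covariance matched filter

For every voxel, the local neighborhood (3 x 3 x 3 by default) is
flattened to a vector and scored against a background covariance model
$R_v = \mathbb E[(v-\bar v)(v -\bar v)^T]$ estimated from sampled
neighborhoods. The filter $h$ maximizing the generalized SNR
$|h^T s|^2 / (h^T R_v h)$ is $h \propto R_v^{-1} s$ (Cauchy–Schwarz on
the whitened vectors), attaining the energy

$$E_p = s^T (R_v + \varepsilon I)^{-1} s ,$$

which is what the energy map stores. $\varepsilon$ is a diagonal
loading, $10^{-6}\,\mathrm{tr}(R_v)/p$ by default, escalated with a
warning when the estimate is singular (for example on constant data);
it exists because $R_v^{-1}$ is otherwise undefined for flat regions.
Conjugate transposes degenerate to transposes throughout: MRI magnitude
images are real.

Two centerings of $s$ are supported, and the distinction matters:

* **patch centering** (`matchedFilterEnergy` default): $s$ is the
  neighborhood minus its own mean. The energy is then an exact
  quadratic form in the input — scaling the channel by $c$ scales
  $E_p$ by $c^2$, constant offsets vanish identically — and measures
  pure local texture.
* **model centering** (`enhanceVolume` default): $s$ is the
  neighborhood minus the covariance model's mean vector, i.e. a
  Mahalanobis deviation from background statistics. A uniformly bright
  lesion interior, which has no texture, still scores high because its
  brightness is itself anomalous. This is the behavior a tumor
  enhancer needs, so the composed pipeline uses it; offset invariance
  still holds there because the model mean is re-estimated from the
  same (offset) channel.

Neighborhood vectors for a given axial slab come from the preceding
slab (the first slab uses the rest of the volume), so each slab is
scored against statistics it did not itself contribute to; `"global"`
and `"identity"` covariance modes are available. Per-channel energy
maps are averaged into one map, and a percentile threshold (95th by
default) gates the candidate-tumor mask.

### Order of stages

The composed stage is wavelet $\to$ PCA compression $\to$
reconstruction $\to$ matched filter, and the network consumes the
reconstructed channels plus the energy map. A configuration flag
bypasses PCA entirely.

## The network

The 3D attention U-Net is built from encoder levels (two 3 x 3 x 3
convolution + instance-norm + ReLU blocks, then 2 x average pooling), a
two-block bottleneck, and decoder levels that upsample
(nearest-neighbor), concatenate the matching encoder skip, apply the
attention module, and convolve back down. A 1 x 1 x 1 convolution and a
per-voxel softmax produce class probabilities.

The **attention module** combines a spatial gate (1 x 1 x 1 convolution
across channels, logistic sigmoid, an $H \times W \times D \times 1$
map) and a channel gate (global average pooling, dense layer, sigmoid,
a $1 \times 1 \times 1 \times C$ vector) multiplicatively, and adds the
result to the identity path:

$$\mathrm{out} = x + x \odot \sigma_{\mathrm{spatial}}
  \odot \sigma_{\mathrm{channel}} .$$

The additive bypass keeps gradients flowing when the parallel gates
saturate; with both maps at zero the module is exactly the identity,
which the tests assert bit-for-bit. Gate weights initialize to zero, so
training starts from flat (0.5) gates.

All forward and backward passes are written out explicitly — the
convolution kernels in C++, everything else in vectorized R — and the
convolution gradients are validated two independent ways: against a
pure-R reference implementation of the single-channel valid convolution
and its hand-derived backward equations, and against central finite
differences. The adjoint identity
$\langle \mathrm{conv}(y,\omega), g\rangle =
\langle y, \mathrm{conv}^T(g,\omega)\rangle$ is asserted as well.

### Defaults, and why they are small

`unetConfig()` defaults to depth 2, 8 base filters, instance
normalization and 24³ training patches. These are deliberately
desk-scale choices: the whole phantom-recovery exercise — generation,
enhancement, 500 optimization steps, held-out evaluation — runs in a
few minutes on one CPU core. Every choice is config-exposed; a
BraTS-scale instantiation (depth 4, 16+ base filters, 64³+ patches,
larger step budgets) is the same code with different numbers, but needs
GPU-class hardware to be practical.

One operational consequence of instance normalization is worth knowing:
its statistics are computed per inference window, so predictions are
most accurate when the inference window size matches the training patch
size. Sliding-window inference with overlap averaging
(`segmentVolume`) handles full volumes; the validation helper defaults
to whole-volume windows, which works well for the centered phantom
tumors, while the capacity checks use matched windows.

### Training

`trainModel` minimizes soft-Dice (over the foreground classes) plus
cross-entropy with equal weights, using Adam (learning rate $10^{-3}$;
doubling it destabilized the small-network optimization in our checks)
and one randomly placed patch per step, centered on a random tumor
voxel with probability 0.5 (foreground oversampling — without it,
background patches dominate and convergence stalls). All randomness
goes through R's RNG, so a fixed seed reproduces a run bit-for-bit. A
non-finite loss aborts with a diagnostic rather than continuing
silently. With a validation set, mean whole-tumor Dice is tracked and
the best-scoring parameters are returned.

## Evaluation battery

Per region (ET, TC, WT): Dice overlap, robust Hausdorff, sensitivity
and specificity. Hausdorff is the 95th-percentile symmetric surface
distance in mm (6-connectivity surfaces, voxel spacing respected), the
robust variant standard in BraTS evaluation; the classical maximum is
available via `percentile = 100`. Conventions for degenerate cases
follow BraTS practice and are warned about when triggered: both-empty
regions count as perfect (Dice 1, distance 0), a single empty region
returns a penalty distance (volume diagonal by default), and undefined
sensitivity/specificity ratios return 0.

The pixel-level confusion matrix is computed on the binary
tumor/non-tumor task (any non-zero label vs background) and always
conserves the total voxel count; accuracy, precision, recall and F1
derive from it. Dataset-level aggregation reports mean, standard
deviation and median per metric per region and is invariant to case
order.

## The phantom generator

`generatePhantom` emulates one BraTS-layout case: a brain ellipsoid
with a smooth (logistic, ~2 voxel) edge profile, containing three
nested tumor ellipsoids — edema ⊃ core ⊃ enhancing — whose semi-axes
are sampled from non-overlapping ranges so the nesting is guaranteed by
construction. Per-modality intensities follow the qualitative BraTS
contrast pattern (edema bright on Flair/T2, enhancing tumor bright on
T1ce, core dark on T1) with additive Gaussian noise; the default noise
s.d. (3 intensity units) is 5% of the nominal 60-unit tumor–tissue
contrast. Default volumes are 64³ voxels at 1 mm spacing; the BraTS
dimensions 240 x 240 x 155 are a configuration away. Everything is
fully determined by `(seed, caseIndex)`.

The smooth brain edge is a modeling choice with a measurable purpose: a
hard air/tissue step creates a high-gradient ring whose matched-filter
energy would dominate the volume mean and mask the lesion signal; real
skull-stripped MRI does not have a one-voxel step either.

What the phantoms do **not** model: MR physics (bias fields, partial
volume, Rician noise), lesion texture, mass effect, or anatomical
variability. Passing the recovery tests therefore demonstrates that the
pipeline's machinery — enhancement, optimization, inference, metrics —
is correct and has the capacity to learn contrast-defined nested
structures; it says nothing about segmentation accuracy on clinical
data, which would require the real dataset and full-scale training.

## Numerical choices and degenerate inputs

* Wavelet: periodized orthonormal filters; dyadic divisibility is
  enforced with a clear error rather than implicit padding.
* Power iteration: relative residual tolerance $10^{-13}$, iteration
  cap $10^5$, deterministic start (strongest column) and sign.
* Covariance: symmetrized before factorization; Cholesky decides
  positive definiteness; automatic ridge escalation warns.
* Energies are clamped at zero against rounding (they are
  mathematically non-negative).
* Softmax rows are max-shifted; cross-entropy clamps probabilities at
  $10^{-12}$; soft-Dice uses an $\varepsilon$ of $10^{-5}$ in numerator
  and denominator.
* Ties in the per-voxel argmax resolve to the first (lowest-index)
  class deterministically.
* Masks validate their label set on construction; unknown labels are
  an error naming the offending values.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run, by design, at sizes a
single CPU core handles comfortably: 64³ phantoms (8 training, 2 held
out, 500 optimization steps) for segmentation recovery, a 48³ phantom
for the single-case capacity check, 16³–40³ volumes for the
enhancement-stage properties, and ≤ 8³ tensors for the
finite-difference gradient sweeps. These sizes are the package's
default study conditions; scaling any of them up changes cost, not
code.

## Known limitations

* The trainable network runs on CPU only; it is sized for method
  validation, not leaderboard training.
* Instance-norm window sensitivity (above) means inference windows
  should match training patches for best boundary accuracy.
* The matched filter's slab-wise covariance assumes the axial slab
  above a voxel is representative background; pathologies spanning
  most of the volume would violate that.
* NIfTI-1 is the only on-disk format; no registration, resampling or
  bias-field correction is performed.
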