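# BrainSeg3D

Automated 3D brain-tumor segmentation from multimodal MRI, built around
two ideas: a deterministic per-slice *enhancement model* that makes
tumor voxels statistically conspicuous before any learning happens, and
a compact *3D attention U-Net* that turns the enhanced volume into a
voxel-wise label map. The package targets the BraTS data convention —
four co-registered channels (Flair, T1, T1ce, T2) per case, integer
labels 1/2/4 for the necrotic core, edema and enhancing tumor, and the
nested evaluation regions ET ⊆ TC ⊆ WT — and ships a synthetic phantom
generator so the entire pipeline can be built, trained and evaluated
with no dataset download.

## The model in brief

**Enhancement.** Each axial slice of each channel is decomposed by an
orthonormal discrete wavelet transform into an approximation band
*W<sub>φ</sub>* and detail bands *W<sub>ψ</sub><sup>i</sup>*,
i ∈ {H, V, D}. The detail coefficients of the slice stack may be
compressed by deflation PCA — components extracted sequentially, each
maximizing ‖X̂<sub>i</sub>w‖² on the deflated matrix
X̂<sub>i</sub> = X − Σ<sub>s&lt;i</sub> X w<sub>s</sub>w<sub>s</sub><sup>T</sup>,
equivalent to the dominant eigenvectors of XᵀX — and the slices are
reconstructed (the transform is perfect-reconstruction, so with PCA
disabled this stage is exactly lossless). A covariance matched filter
then scores every voxel: with R<sub>v</sub> the covariance of
background neighborhood vectors and s the voxel's (centered)
neighborhood, the optimal whitened filter h ∝ R<sub>v</sub>⁻¹s attains
the energy

> E<sub>p</sub> = sᵀ (R<sub>v</sub> + εI)⁻¹ s,

stored as a per-voxel energy map whose upper percentile gates candidate
tumor voxels.

**Segmentation.** The enhanced channels plus the energy map (5 input
channels) feed a 3D U-Net whose decoder levels apply a
channel-plus-spatial attention module with an additive bypass:
out = x + x ⊙ σ<sub>spatial</sub> ⊙ σ<sub>channel</sub>. Training
minimizes soft-Dice + cross-entropy with Adam on randomly placed,
tumor-oversampled patches. All forward *and backward* passes are
implemented in the package (C++ convolution kernels, vectorized R
elsewhere) and validated against a pure-R reference convolution,
central finite differences, and the adjoint identity.

**Evaluation.** Dice, 95th-percentile symmetric surface distance (mm),
sensitivity and specificity per ET/TC/WT region; binary pixel-level
confusion matrix with accuracy/precision/recall/F1; per-dataset
mean/stddev/median aggregation.

## Worked example

Generate a phantom case, enhance it, and inspect what the matched
filter sees:

```r
library(BrainSeg3D)

cfg <- phantomConfig(nCases = 3)        # 64^3 voxels, BraTS-style labels
ph  <- generatePhantom(cfg, 1)
ph$volume
#> MultiModalVolume: 4 channel(s) [flair, t1, t1ce, t2], grid 64x64x64
#>   spacing (mm): 1 x 1 x 1
#>   intensity range: [-14.65, 170.9]
ph$mask
#> SegmentationMask: grid 64x64x64, labels {1, 2, 4}
#>   voxel counts: 0=253740 1=2158 2=6094 4=152
#>   regions: ET={4} TC={1,4} WT={1,2,4}

enh <- enhanceVolume(ph$volume, enhanceConfig())
enh$energy
#> EnhancedVolume: grid 64x64x64, energy range [2.24, 1803]
#>   threshold 60.25 -> 13108 candidate voxel(s)

wt <- regionMasks(ph$mask)$WT
E  <- energyMap(enh$energy)
mean(E[wt]) / mean(E[!wt])
#> [1] 5.0
```

The tumor's mean matched-filter energy is five times the background's
before the network has seen a single example — that separation is what
the enhancement stage contributes.

Training and evaluating the network on a small phantom cohort (about
five minutes on one CPU core):

```r
cases <- lapply(1:10, function(i) {
  p <- generatePhantom(phantomConfig(), i)
  prepareCase(p$volume, p$mask)          # enhance + assemble 5-channel input
})
model <- buildModel(unetConfig(), seed = 0)
model
#> 3D attention U-Net: depth 2, base 8, in 5 -> classes 4 (instance norm)
#>   50 parameter tensors, 92750 parameters

fit <- trainModel(model, cases[1:8], trainConfig(steps = 500, seed = 0),
                  valCases = cases[9:10], verbose = TRUE)
#> step 100  loss 2.3619  val WT Dice 0.180
#> step 200  loss 0.6580  val WT Dice 0.662
#> step 300  loss 0.6040  val WT Dice 0.794
#> step 400  loss 1.1660  val WT Dice 0.930
#> step 500  loss 0.8630  val WT Dice 0.949
```

A whole-tumor Dice of 0.95 on held-out phantoms after 500 steps means
the network recovers the labeled geometry almost voxel-perfectly from
the enhanced channels. `segmentVolume()` runs sliding-window inference
on full volumes; `evaluateCase()` produces the per-region metric table
and pixel confusion.

Disk-based workflows (`generateDataset()`, `loadCase()`, `writeMask()`)
use NIfTI-1 files in the BraTS one-directory-per-case layout, and
`inst/scripts/brainseg` wraps the same functions as a command line
(`simulate`, `enhance`, `train`, `predict`, `evaluate`, `gradcheck`).

## Scope and limits

The phantoms are ellipsoidal and noise-simple by design: they validate
the mathematics, the gradients, the optimization and the metrics, not
clinical accuracy. Reproducing BraTS leaderboard numbers would require
the registered dataset and GPU-scale training, both outside this
package's scope; the network defaults are correspondingly desk-scale
(depth 2, 8 base filters) and every architectural choice is exposed in
`unetConfig()`. See the methods vignette
(`vignettes/BrainSeg3D-methods.Rmd`) for the full account of the model,
its assumptions and its numerical choices.
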