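---
title: "Two-stage pectoralis muscle volumetry: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage pectoralis muscle volumetry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the two-stage design

The pectoralis major is a large anterior chest-wall muscle whose CT-derived
volume and density are used as biomarkers for COPD severity and sarcopenia.
Segmenting it from a whole chest CT is awkward for a single voxel-wise
model: the muscle occupies a small fraction of the scan, so a 3D
segmentation network sees an extreme class imbalance and tends to leak into
the abdomen and shoulders.

`pectovol` therefore splits the task in two:

1. **Range detection.** A compact convolutional classifier looks at the
   whole scan — reduced to a 3-channel coronal projection — and predicts,
   for each vertical position, whether the pectoralis is present. The
   longest contiguous run of positive bins becomes the detected slice
   range.
2. **Slice segmentation.** An attention-gated U-Net segments the muscle on
   each *original* axial slice inside that range. The axial slices are
   deliberately used as acquired — no resampling or filtering on the
   segmentation path — because HU distributions are physically calibrated
   and interpolation distorts them.

Post-processing (per-slice small-component removal, morphological closing
and hole filling, 3D connectivity filtering, inter-slice gap interpolation)
turns the per-slice predictions into one coherent bilateral muscle volume,
which is then quantified (volume in cc, mean density in HU).

## Range detection in detail

The detector input is a *fused multichannel coronal image*. The CT is first
resampled to an isotropic grid (default 2 mm) so that the coronal plane is
not distorted by slice thickness; three coronal planes are then sampled at
anteroposterior fractions 3/8, 4/8 and 5/8 of the body extent ("half of a
quarter" steps around the mid-coronal plane, where the pectoralis lies) and
stacked as channels. Training augments each case by re-extracting the
image at rigidly jittered positions (one shared offset per triple, default
at most 1/16 of the extent); prediction extracts five jittered views,
binarizes each per-bin sigmoid output at 0.5, and takes the element-wise
median across views. The median vote suppresses single-view leakage above
or below the muscle.

The encoder is a small stack of conv/batch-norm/ReLU/max-pool blocks with
compound width/depth scaling (defaults: width multiplier 0.25 giving
8/16/32 channels, depth 3). An adaptive average-pooling layer reduces the
feature map to a fixed 8 x 4 grid regardless of input size — scan lengths
vary between acquisitions, and the head must not care — followed by dropout
0.3 and one linear layer to 128 output bins. Binary cross-entropy with
logits is the training objective; each bin is an independent presence
decision. Labels (one bit per isotropic slice, derived by projecting the
ground-truth mask onto the z axis) are nearest-resampled to the 128 bins,
and predicted probabilities are nearest-resampled back; the fixed bin count
decouples the head from the scan length, and nearest resampling keeps
labels binary.

Detected intervals are half-open and 1-based throughout the package. The
iso-grid interval maps back to original slices via
`floor((z_iso - 1) * iso_mm / slice_thickness) + 1`, clamped to the volume.

## The segmentation network

The U-Net follows the classic two-convolutions-per-level pattern
(3 x 3 kernels, batch norm, ReLU), 2 x 2 max pooling on the way down and
nearest-neighbour upsampling followed by a 3 x 3 convolution on the way up.
The reference configuration has 6 levels with channels doubling from 16 up
to a 512 cap. Each skip connection passes through an additive attention
gate — `alpha = sigmoid(psi(relu(Wg g + Wx x)))`, with the coarser decoder
feature as the gating signal — so the decoder can suppress irrelevant
anatomy before concatenation; one more spatial attention block sits on the
final feature map. Soft Dice loss (epsilon-smoothed, `1e-6`) is the
objective: it is insensitive to the foreground/background imbalance, and
the smoothing defines the empty-vs-empty case as a perfect (zero-loss)
prediction, which matters for slices near the range boundary.

The networks, backpropagation and the Adam optimizer are implemented
natively in this package (R orchestration over C++ im2col convolution
kernels); analytic gradients are verified against numerical differentiation
in the test suite. Optimizer defaults — Adam, learning rate `1e-3` (`2e-3`
for the segmentation runs in the experiments, which converges faster at
these problem sizes), batch 8 — are exposed in the training functions.
Training is deterministic given a seed: same seed, same loss history,
same weights.

## Post-processing choices

* 2D components use 8-connectivity, 3D ones 26-connectivity — the standard
  choice for blob-like anatomy. The area cutoff (default 50 px) removes
  speckle without touching plausible muscle fragments.
* `keep_components = 2` reflects bilateral anatomy: one component per side.
  Note that the 3D filter runs *before* gap interpolation (the stage order
  of the method), so a mask with a fully dropped mid-slice is split into
  more pieces at filtering time; the component count is configurable for
  such inputs.
* Inter-slice interpolation is shape-based: an empty slice flanked by
  segmented slices (runs up to `max_gap`, default 1) is filled by averaging
  the flanking signed Euclidean distance maps and thresholding at zero.
  Identical flanks reproduce themselves exactly; differing flanks produce a
  smooth intermediate contour. Voxel voting was rejected because it cannot
  produce transitional shapes.
* Closing radius 2 px smooths boundaries and, with hole filling, removes
  interior defects; closing and hole filling are the only extensive steps,
  everything else only removes voxels.

## Quantification and follow-up comparison

Muscle volume is the per-slice foreground area (`count * sx * sy`) summed
over slices and multiplied by the slice thickness; this equals
`voxel_count * sx * sy * sz` exactly, and is reported in cc. Density is the
mean HU over the whole mask (the volume of interest; no core erosion is
applied). Follow-up pairs are compared as `100 * pre / post` percent ratios
for volume and density plus absolute differences — the ratio orientation is
fixed; pass the earlier scan as `pre`.

Outlier screening replaces visual review with a reproducible statistical
rule: a pair is flagged when its volume ratio deviates from the center of
the *other* pairs' ratios by more than `k = 2` of their standard
deviations. The leave-one-out formulation matters: a single gross outlier
inflates the pooled SD enough to mask itself (with ratios
100/98/102/100/300 the pooled 2-SD band is just over 160 and the 300 would
survive), whereas against the other four alone it is hundreds of SDs out.

## What the phantom generator emulates — and what it does not

The generator produces axial chest-CT look-alikes with exact ground truth:
an elliptical soft-tissue body (40 HU) with a subcutaneous fat rim
(-100 HU), two lung fields (-800 HU), spine and rib bone (700 HU) in air
(-1000 HU), and paired anterior muscle crescents (55 HU) present only
within a chosen fraction of the z extent. Defaults are 64 x 96 x 96 voxels
at (1.5, 1.5, 3) mm — 3 mm slices as in routine chest protocols — with
crescent thickness 10 px (~15 mm, a realistic pectoralis thickness) spanning
a muscle z-fraction drawn from roughly the middle of the scan. Additive
Gaussian noise models the dose class: 10 HU for normal-dose and 25 HU for
low-dose scans, and generated cohorts are 70 % low-dose, matching the
make-up of a modern screening population. Optional distractor blobs share
the muscle HU but are disjoint from the label, exercising the 3D
connectivity filter; an optional "mammary blob" fixture mimics the known
soft-tissue leakage failure mode.

The crescent geometry is deliberately *not* anatomically faithful. It was
chosen so that (a) the left/right components are separable by connectivity,
(b) the true cross-section area is computable independently of the voxel
mask (by super-sampled rasterization of the analytic construction), and
(c) the muscle/soft-tissue contrast is the genuinely hard part: at 15 HU
contrast against up to 25 HU noise, per-voxel thresholding is hopeless and
the network must learn shape and context. Passing the phantom experiments
therefore demonstrates that the pipeline machinery — fusion, detection,
median voting, slice segmentation, cleanup, quantification — is correct and
trainable, not that the shipped configuration reaches clinical accuracy on
hospital data. Real CT physics (beam hardening, reconstruction kernels,
anatomy variability, truncated fields of view) is out of scope.

Follow-up pairs perturb the baseline phantom by scaling the crescent
thickness (cross-section area, and hence volume, scales approximately
linearly), a rigid in-plane shift, and a noise-level change — the small
physiological and acquisition changes expected between two scans taken a
few weeks apart.

## Experiment sizing

`phantom_recovery_experiment()` is the package's end-to-end study: train
both models on a randomized phantom cohort, evaluate on held-out phantoms,
and report the range-endpoint mean absolute error (in original slices) and
the mean Dice coefficient of the final masks. The default sizes — 150
training phantoms, 3 fused views each for the detector, 400 axial training
slices, 8 and 6 epochs, 30 held-out phantoms, with the toy model
configurations (detector width 0.25/depth 3/128 bins; U-Net with 4 levels,
8-64 channels) — were chosen so the full experiment completes in minutes on
a single CPU core while leaving every stage of the method load-bearing.
With these settings the experiment reaches endpoint errors of about one
slice and mean Dice above 0.9; the test suite asserts the looser
thresholds of 3 slices and 0.80.

## Numerical and degenerate-case conventions

* Resampling uses the voxel-edge extent rule `n' = round(n * s / target)`
  (minimum 1), preserving each axis's physical extent to within one target
  voxel; CT interpolates linearly, masks by nearest neighbour.
* The intensity window default (-200, 300) HU brackets fat through dense
  muscle and bone onset; values outside clip to 0/1.
* Binarization thresholds are 0.5 everywhere (range bins and segmentation
  probabilities).
* An even number of median votes ties at 0.5; the tie rounds up to 1
  (the default view count, 5, is odd, so this is a convention rather than a
  common path).
* An all-zero median vote yields an empty interval, a warning, and an empty
  mask with a well-formed report rather than an error.
* Empty-vs-empty agreement metrics (Dice, IoU, precision) are defined as 1.
* Mask NIfTI files are written as unsigned 8-bit (bit-exact round trips);
  CT as float32.
* DICOM series input is not supported; NIfTI is the package's on-disk
  format for volumes and masks.
* The commercial denoiser used in clinical preprocessing pipelines is out
  of scope; `denoise()` offers generic Gaussian/median smoothing and
  defaults to off.

## Known limitations

* The shipped configurations are desk-scale: they demonstrate and test the
  method, and transfer learning from them is supported
  (`init_weights`, `active_learning_round()`), but clinical-grade accuracy
  requires training at full scale on real annotated CT.
* Range detection assumes one contiguous muscle extent; multi-segment
  ranges collapse to the longest run.
* Visual grades are stored as user-supplied metadata only; the 1-10 scale
  is never computed by the package.
* Truncated fields of view are only surfaced as warnings/empty results,
  not corrected.
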