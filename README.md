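# pectovol — two-stage pectoralis muscle volumetry from chest CT

The pectoralis major is a large anterior chest-wall muscle whose CT-derived
volume and density track respiratory muscle function; they are used as
imaging biomarkers for COPD severity and sarcopenia. Measuring them by hand
— slice-by-slice contouring of the muscle across a chest CT — is slow and
operator-dependent, and a single 3D segmentation model struggles with the
extreme class imbalance of a small muscle inside a whole-thorax scan.

`pectovol` implements a two-stage deep-learning pipeline for the task, for
researchers quantifying body composition on chest CT:

1. **Vertical range detection.** The CT volume is resampled isotropically
   and reduced to a 3-channel image of coronal planes sampled at
   anteroposterior fractions 3/8, 4/8, 5/8 of the body. A compact
   convolutional classifier with an adaptive-pooling head maps this fused
   image (of any size) to per-position presence logits, trained with
   binary cross-entropy on logits:

   `L = mean_z [ max(l_z, 0) − l_z y_z + log(1 + e^−|l_z|) ]`

   At prediction time five rigidly jittered views are binarized at 0.5 and
   combined by an element-wise median; the longest run of positive bins is
   the detected axial range.

2. **Slice segmentation.** An attention-gated U-Net (two 3×3 conv +
   batch-norm + ReLU per level, 2×2 pooling/upsampling, additive attention
   gates `α = σ(ψ(ReLU(W_g g + W_x x)))` on the skip connections and a
   final spatial attention block) segments each original axial slice inside
   the range, trained with the soft Dice loss
   `L = 1 − (2 Σ p t + ε) / (Σ p + Σ t + ε)`.

Per-slice predictions are cleaned by small-component removal, morphological
closing and hole filling, a 3D connectivity filter keeping the two largest
(bilateral) components, and signed-distance inter-slice interpolation; the
result is quantified as volume `Σ_slices area · slice-thickness` (cc) and
mean density (HU), with follow-up pair comparison
(`100 · pre/post` ratios) and a leave-one-out 2-SD outlier screen. Overlap
against reference masks is reported as `DSC = 2|R∩T| / (|R|+|T|)`, IoU,
precision and pixel accuracy.

Both networks, their losses, backpropagation and the Adam optimizer are
implemented natively in the package (R over C++ im2col convolution
kernels), so the pipeline trains and runs on a single CPU with no external
deep-learning framework. A synthetic chest-CT phantom generator with exact
ground truth (body/fat/lung/bone ellipses plus paired anterior muscle
crescents, normal- and low-dose noise levels) makes every stage trainable
and testable without clinical data.

## Worked example

Train the desk-scale configuration on 150 synthetic phantoms, evaluate on
30 held-out phantoms, then segment a fresh low-dose phantom end to end:

```r
library(pectovol)

exp <- phantom_recovery_experiment(seed = 42)   # ~5 min on one CPU core
print(exp)
#> <phantom_recovery> 30 held-out phantoms
#>   range endpoint MAE: 0.13 (lower) / 0.17 (upper) slices
#>   mean Dice 0.986, mean IoU 0.972

ph <- generate_phantom(phantom_spec(seed = 123, dose = "low",
                                    distractor_components = 2))
res <- run_pipeline(ph$ct, pipeline_config(),
                    range_model = exp$range_model,
                    seg_model = exp$seg_model, truth = ph$mask)
print(res$report)
#> <quant_report> case 'phantom_seed123', slices [17, 42)
#> <muscle_quant> 103.65 cc over 15355 voxels, mean density 55.0 HU
#> <segmentation_metrics> DSC 0.9734, IoU 0.9481, precision 0.9943, accuracy 0.9986

quantify_muscle(ph$ct, ph$mask)$volume_cc   # ground truth: 108.108 cc
```

Reading: the detector localized the muscle-bearing slices 17–41 (half-open
interval), the U-Net + post-processing recovered 103.7 cc of the 108.1 cc
true muscle volume at Dice 0.97, and the mean density estimate equals the
phantom's muscle attenuation (55 HU). `run_pipeline()` accepts NIfTI paths
for real CT volumes and masks; `inst/cli/pectovol.R` wraps the same
functions for shell use (`segment`, `phantom`, `train-range`, `train-seg`,
`evaluate`, `followup`, `active-round`).

See `vignettes/pectovol-methods.Rmd` for the models, parameter defaults,
phantom design, and the package's numerical conventions.

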